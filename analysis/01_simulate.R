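#!/usr/bin/env Rscript

# Stage 1: generate the study herd.
#
# Simulates the default desk-scale herd under the age-at-first-calving
# variance regime (~3,000 animals over 5 generations; ~800 recorded
# cows, all genotyped on 1,200 SNPs; 300 herd-year-season classes) and
# writes the analysis fixtures (pedigree CSV, PLINK .ped/.map of the
# genotyped cows, phenotype CSV, truth JSON) under results/sim/.

suppressPackageStartupMessages(library(wssgblup))

cfg <- sim_config(trait_profile = "AFC", seed = 20260930L)
herd <- simulate_herd(cfg)
paths <- write_fixtures(herd, "results/sim")

cat(sprintf("herd: %d animals over %d generations, mean F = %.4f\n",
            nrow(herd$ped), cfg$n_generations, mean(herd$ped$F)))
cat(sprintf("records: %d cows; genotyped: %d; SNPs: %d on %d chromosomes\n",
            nrow(herd$phenotypes),
            length(attr(herd$genotypes, "genotyped_ids")),
            cfg$n_snps, cfg$n_chromosomes))
cat(sprintf("true h2 = %.4f (sigma2_a %.2f / hys %.2f / e %.2f)\n",
            herd$truth$h2, cfg$sigma2_a, cfg$sigma2_hys, cfg$sigma2_e))
cat("wrote:", paste(basename(paths), collapse = ", "), "-> results/sim/\n")
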