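#!/usr/bin/env Rscript

# Stage 2: genotype quality control.
#
# Reads the PLINK text genotypes written by 01_simulate.R and applies
# the QC cascade: autosomes only, individual call rate >= 0.90, then
# minor allele frequency >= 0.01 recomputed on the surviving animals.
# Writes the per-stage drop counts to results/qc_report.tsv.

suppressPackageStartupMessages(library(wssgblup))

g <- read_plink_text("results/sim/genotypes.ped", "results/sim/genotypes.map")
print(g)
qc <- qc_filter(g)
print(qc$report)
write.table(qc$report, "results/qc_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
f <- allele_frequencies(qc$genotypes)
cat(sprintf("post-QC: %d SNPs, MAF in [%.3f, %.3f], sum 2pq = %.1f\n",
            ncol(qc$genotypes$dosage), min(f$maf), max(f$maf), f$two_pq_sum))
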