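# Gene-dropping herd simulator. Generates a discrete-generation beef
# herd (few sires, many dams, half-sib families), drops founder alleles
# down the pedigree (free segregation between loci), and builds phenotype
# records under the exact model the analysis assumes:
#   y = mu + X b + Z a + W c + e
# with a = marker/QTL part (true effects at genotyped loci, gene-dropped
# to every animal) + residual polygenic part (pedigree Mendelian-sampling
# recursion), c the herd-year-season effect, and trait profiles matching
# the fertility traits' fixed-effect layouts and variance regimes. The
# default architecture gives every marker a small effect (whole-panel
# polygenic, 90% of sigma2_a) so that the additive covariance of the
# genotyped animals is their realized genomic relationship -- the
# covariance the single-step model asserts; sparse large-QTL
# architectures for power studies are configured explicitly.

# logical column that tolerates its absence (e.g. hand-built pedigrees)
isTRUE_col <- function(x) {
  if (is.null(x)) return(FALSE)
  !is.na(x) & x == TRUE
}

trait_profiles <- list(
  AFC = list(sigma2_a = 6.29, sigma2_hys = 15.90, sigma2_e = 21.01,
             mean = 35, unit = "months"),
  IC12 = list(sigma2_a = 3.65, sigma2_hys = 2.49, sigma2_e = 8.90,
              mean = 15, unit = "months"),
  ACI = list(sigma2_a = 2.91, sigma2_hys = 1.45, sigma2_e = 6.26,
             mean = 16, unit = "months"),
  RE = list(sigma2_a = 53.38, sigma2_hys = 73.79, sigma2_e = 133.94,
            mean = 70, unit = "%"))

#' Simulation configuration
#'
#' The defaults describe the desk-scale study herd used throughout the
#' package's analyses: ~3,000 animals over 5 discrete generations (600
#' founders; 25 sires and 240 dams per generation, 2 offspring per dam,
#' giving half-sib family structure), 1,200 SNPs on 10 chromosomes of
#' 100 Mb, and 300 herd-year-season classes over ~1,200 cow records
#' (about 4 per class). The ~1,200 non-founder cows all carry records
#' and the genotyped animals are selected from the recorded cows
#' (default two thirds, giving 800 genotyped). Trait profiles select
#' the fixed-effect layout, a plausible trait mean and the variance
#' regime (additive / herd-year-season / residual) typical of
#' low-heritability fertility traits.
#'
#' @param trait_profile `"AFC"`, `"IC12"`, `"ACI"`, `"RE"` or `"custom"`
#'   (custom requires the three variances).
#' @param n_founders,founder_female_frac founder population and its sex
#'   split.
#' @param n_generations,n_sires,n_dams,offspring_per_dam breeding design
#'   per generation (sires reused across dams; random mating).
#' @param n_snps,n_chromosomes,chrom_length_bp marker panel geometry.
#' @param founder_maf_range founder allele frequencies drawn uniformly in
#'   this MAF range.
#' @param n_qtl,qtl_variance_fraction trait architecture: number of marker
#'   loci carrying true effects and the share of the base-population
#'   `sigma2_a` they jointly explain. The default (`NULL` = every marker,
#'   fraction 1) is a whole-panel polygenic architecture: the additive
#'   covariance of the genotyped animals is exactly their realized
#'   genomic relationship, which is what the single-step model asserts.
#'   Set e.g. `n_qtl = 1` with a small fraction to plant one large QTL
#'   over a pedigree-polygenic background, or fraction 0 for a purely
#'   pedigree-polygenic null.
#' @param qtl_maf_min when planting a sparse QTL architecture
#'   (`n_qtl < n_snps`), QTL loci are drawn from markers whose founder
#'   minor allele frequency is at least this (default 0.2): a planted
#'   QTL is meant to be a common causal variant, and a rare one both
#'   drifts out of detectability and can drop out of the panel at QC.
#' @param sigma2_a,sigma2_hys,sigma2_e variance components (trait units
#'   squared); defaults come from the trait profile.
#' @param mean_trait overall mean; default from the trait profile.
#' @param n_hys_classes number of herd-year-season classes.
#' @param recorded_fraction fraction of cows (non-founder females) with
#'   phenotype records, sampled stratified by generation.
#' @param genotyped_fraction fraction of the recorded cows genotyped
#'   (stratified across generations).
#' @param beta_F,beta_age,afc_class_effects true fixed-effect values for
#'   the profiles that include them.
#' @param seed integer seed fixing all randomness end-to-end.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(trait_profile = c("AFC", "IC12", "ACI", "RE", "custom"),
                       n_founders = 600L, founder_female_frac = 0.9,
                       n_generations = 5L, n_sires = 25L, n_dams = 240L,
                       offspring_per_dam = 2L,
                       n_snps = 1200L, n_chromosomes = 10L,
                       chrom_length_bp = 1e8,
                       founder_maf_range = c(0.05, 0.5),
                       n_qtl = NULL, qtl_variance_fraction = 1,
                       qtl_maf_min = 0.2,
                       sigma2_a = NULL, sigma2_hys = NULL, sigma2_e = NULL,
                       mean_trait = NULL, n_hys_classes = 300L,
                       recorded_fraction = 1, genotyped_fraction = 2 / 3,
                       beta_F = 5, beta_age = 0.3,
                       afc_class_effects = c(0, 0.5, 1),
                       seed = 1L) {
  trait_profile <- match.arg(trait_profile)
  prof <- if (trait_profile == "custom") NULL else trait_profiles[[trait_profile]]
  cfg <- list(trait_profile = trait_profile,
              n_founders = as.integer(n_founders),
              founder_female_frac = founder_female_frac,
              n_generations = as.integer(n_generations),
              n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
              offspring_per_dam = as.integer(offspring_per_dam),
              n_snps = as.integer(n_snps),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = chrom_length_bp,
              founder_maf_range = founder_maf_range,
              n_qtl = as.integer(n_qtl %||% n_snps),
              qtl_variance_fraction = qtl_variance_fraction,
              qtl_maf_min = qtl_maf_min,
              sigma2_a = sigma2_a %||% prof$sigma2_a,
              sigma2_hys = sigma2_hys %||% prof$sigma2_hys,
              sigma2_e = sigma2_e %||% prof$sigma2_e,
              mean_trait = mean_trait %||% prof$mean %||% 0,
              n_hys_classes = as.integer(n_hys_classes),
              recorded_fraction = recorded_fraction,
              genotyped_fraction = genotyped_fraction,
              beta_F = beta_F, beta_age = beta_age,
              afc_class_effects = afc_class_effects,
              seed = as.integer(seed))
  if (is.null(cfg$sigma2_a) || is.null(cfg$sigma2_hys) || is.null(cfg$sigma2_e))
    stop("custom trait profile requires sigma2_a, sigma2_hys and sigma2_e")
  stopifnot(cfg$sigma2_a >= 0, cfg$sigma2_hys >= 0, cfg$sigma2_e >= 0,
            cfg$qtl_variance_fraction >= 0, cfg$qtl_variance_fraction <= 1,
            cfg$genotyped_fraction >= 0, cfg$genotyped_fraction <= 1,
            cfg$recorded_fraction >= 0, cfg$recorded_fraction <= 1,
            cfg$n_snps %% cfg$n_chromosomes == 0)
  structure(cfg, class = "sim_config")
}

#' Simulate a discrete-generation herd pedigree
#'
#' Each generation draws `n_sires` sires and `n_dams` dams from the
#' previous generation (or fewer, if fewer are available); every dam
#' produces `offspring_per_dam` offspring by a randomly assigned sire,
#' with sires reused across dams (paternal half-sib families). Offspring
#' sex is random. Inbreeding accumulates by drift through the finite
#' sire pool.
#'
#' @param cfg [sim_config()].
#' @return sorted `pedigree_table` with `sex` (`"F"`/`"M"`) and
#'   `generation` columns and inbreeding computed.
#' @export
simulate_pedigree <- function(cfg) {
  set.seed(cfg$seed)
  nf <- cfg$n_founders
  n_fem <- round(nf * cfg$founder_female_frac)
  id <- sprintf("G0_%05d", seq_len(nf))
  sex <- rep(c("F", "M"), c(n_fem, nf - n_fem))
  rec <- data.frame(animal = id, sire = "", dam = "",
                    sex = sex, generation = 0L, stringsAsFactors = FALSE)
  prev <- rec
  for (g in seq_len(cfg$n_generations)) {
    males <- prev$animal[prev$sex == "M"]
    females <- prev$animal[prev$sex == "F"]
    if (!length(males) || !length(females))
      stop("generation ", g, " has no available sires or dams")
    sires <- if (length(males) > cfg$n_sires)
      sample(males, cfg$n_sires) else males
    dams <- if (length(females) > cfg$n_dams)
      sample(females, cfg$n_dams) else females
    dam_of <- rep(dams, each = cfg$offspring_per_dam)
    sire_of <- rep(sample(sires, length(dams), replace = TRUE),
                   each = cfg$offspring_per_dam)
    n_off <- length(dam_of)
    off <- data.frame(
      animal = sprintf("G%d_%05d", g, seq_len(n_off)),
      sire = sire_of, dam = dam_of,
      sex = ifelse(stats::runif(n_off) < 0.5, "F", "M"),
      generation = g, stringsAsFactors = FALSE)
    rec <- rbind(rec, off)
    prev <- off
  }
  ped <- compute_inbreeding(as_pedigree_table(rec))
  # performance-recorded subset of the cows, stratified by generation
  cows <- ped$id[ped$sex == "F" & ped$generation > 0L]
  gen <- ped$generation[match(cows, ped$id)]
  recorded <- unlist(lapply(split(cows, gen), function(ids) {
    k <- round(length(ids) * cfg$recorded_fraction)
    if (k > 0) sample(ids, k) else character(0)
  }), use.names = FALSE)
  ped$recorded <- ped$id %in% recorded
  ped
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder haplotypes are drawn under Hardy-Weinberg at per-SNP
#' frequencies uniform in the configured MAF range; each non-founder
#' inherits, per locus independently (free segregation; no linkage
#' model), one random allele from each parent. Map positions are uniform
#' within equal-length chromosomes. A genotyped subset of the recorded
#' cows (non-founder females) is sampled stratified by generation so all
#' generations are represented.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param cfg [sim_config()].
#' @return [genotype_matrix()] of ALL animals (analysis code subsets with
#'   [subset_genotypes()]), with attributes `genotyped_ids` and
#'   `founder_freq`.
#' @export
simulate_genotypes <- function(ped, cfg) {
  set.seed(cfg$seed + 1L)
  n <- nrow(ped); m <- cfg$n_snps
  per_chr <- m / cfg$n_chromosomes
  map <- data.frame(
    snp = sprintf("snp%05d", seq_len(m)),
    chrom = as.character(rep(seq_len(cfg$n_chromosomes), each = per_chr)),
    pos = as.vector(vapply(seq_len(cfg$n_chromosomes), function(i)
      sort(sample.int(cfg$chrom_length_bp, per_chr)), integer(per_chr))))
  p <- stats::runif(m, cfg$founder_maf_range[1], cfg$founder_maf_range[2])
  alle <- t(vapply(seq_len(m), function(j) sample(c("A", "C", "G", "T"), 2),
                   character(2)))

  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  founders <- which(ped$sire_code == 0L & ped$dam_code == 0L)
  H1[founders, ] <- stats::rbinom(length(founders) * m, 1L, rep(p, each = length(founders)))
  H2[founders, ] <- stats::rbinom(length(founders) * m, 1L, rep(p, each = length(founders)))
  for (i in seq_len(n)) {
    s <- ped$sire_code[i]; d <- ped$dam_code[i]
    if (!s && !d) next
    # both parents known in simulated pedigrees
    pick_s <- stats::runif(m) < 0.5
    H1[i, ] <- ifelse(pick_s, H1[s, ], H2[s, ])
    pick_d <- stats::runif(m) < 0.5
    H2[i, ] <- ifelse(pick_d, H1[d, ], H2[d, ])
  }
  dosage <- H1 + H2
  rownames(dosage) <- ped$id

  rec_cows <- ped$id[isTRUE_col(ped$recorded)]
  gen <- ped$generation[match(rec_cows, ped$id)]
  genotyped <- unlist(lapply(split(rec_cows, gen), function(ids) {
    k <- round(length(ids) * cfg$genotyped_fraction)
    if (k > 0) sample(ids, k) else character(0)
  }), use.names = FALSE)
  g <- genotype_matrix(dosage, map,
                       counted_allele = alle[, 1], other_allele = alle[, 2])
  attr(g, "genotyped_ids") <- ped$id[ped$id %in% genotyped]
  attr(g, "founder_freq") <- p
  g
}

#' Simulate phenotype records and the underlying truth
#'
#' Breeding values are the sum of a planted-QTL part (effects at
#' `n_qtl` marker loci, rescaled so their realized population variance is
#' `qtl_variance_fraction * sigma2_a`) and a residual polygenic part from
#' the pedigree recursion `a_i = (a_s + a_d)/2 + m_i`,
#' `m_i ~ N(0, d_i^F sigma2_poly)` with the inbreeding-adjusted Mendelian
#' sampling variance. Records are produced for every non-founder female
#' ("cow"): overall mean, the trait profile's true fixed effects, the
#' breeding value, a herd-year-season effect (`N(0, sigma2_hys)`, classes
#' assigned at random), and residual noise.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param genotypes all-animal genotypes from [simulate_genotypes()].
#' @param cfg [sim_config()].
#' @return list with `phenotypes` (data.frame `animal`, `value`, `hys`,
#'   `F`, `age_last_calving`, `afc_class`) and `truth` (per-animal
#'   breeding values, QTL table, HYS effects, true fixed effects).
#' @export
simulate_phenotypes <- function(ped, genotypes, cfg) {
  set.seed(cfg$seed + 2L)
  n <- nrow(ped)
  frac <- cfg$qtl_variance_fraction
  u_qtl <- numeric(n)
  qtl <- NULL
  if (cfg$n_qtl > 0L && frac > 0) {
    qtl_idx <- if (cfg$n_qtl == cfg$n_snps) seq_len(cfg$n_snps) else {
      pf <- attr(genotypes, "founder_freq")
      common <- which(pmin(pf, 1 - pf) >= cfg$qtl_maf_min)
      if (length(common) < cfg$n_qtl)
        stop("fewer than n_qtl markers satisfy qtl_maf_min")
      sort(sample(common, cfg$n_qtl))
    }
    beta <- stats::rnorm(cfg$n_qtl)
    raw <- drop(genotypes$dosage[ped$id, qtl_idx, drop = FALSE] %*% beta)
    # additive variance refers to the founder (base) population
    founders <- ped$sire_code == 0L & ped$dam_code == 0L
    raw_var <- mean((raw[founders] - mean(raw[founders]))^2)
    scale <- sqrt(frac * cfg$sigma2_a / raw_var)
    u_qtl <- (raw - mean(raw)) * scale
    qtl <- data.frame(snp = genotypes$map$snp[qtl_idx],
                      chrom = genotypes$map$chrom[qtl_idx],
                      pos = genotypes$map$pos[qtl_idx],
                      effect = beta * scale)
  }
  s2_poly <- (1 - frac) * cfg$sigma2_a
  u_poly <- numeric(n)
  if (s2_poly > 0) {
    dmend <- mendelian_d(ped)
    ms <- stats::rnorm(n, 0, sqrt(s2_poly * dmend))
    s <- ped$sire_code; d <- ped$dam_code
    for (i in seq_len(n)) {
      pa <- 0
      if (s[i]) pa <- pa + 0.5 * u_poly[s[i]]
      if (d[i]) pa <- pa + 0.5 * u_poly[d[i]]
      u_poly[i] <- pa + ms[i]
    }
  }
  u <- u_qtl + u_poly

  cows <- which(isTRUE_col(ped$recorded))
  nr <- length(cows)
  hys_class <- sample.int(cfg$n_hys_classes, nr, replace = TRUE)
  hys_eff <- stats::rnorm(cfg$n_hys_classes, 0, sqrt(cfg$sigma2_hys))
  # dense recode of the observed classes
  hys_f <- factor(hys_class)
  afc_months <- pmin(pmax(stats::rnorm(nr, 35, 6.7), 17), 49)
  age_lc <- stats::rnorm(nr, 9, 2.5)
  cls <- afc_class(afc_months)

  spec <- trait_model_spec(if (cfg$trait_profile == "custom") "custom"
                           else cfg$trait_profile)
  fixed <- rep(cfg$mean_trait, nr)
  if ("F" %in% spec$covariates) fixed <- fixed + cfg$beta_F * ped$F[cows]
  if ("age_last_calving" %in% spec$covariates)
    fixed <- fixed + cfg$beta_age * age_lc
  if ("afc_class" %in% spec$factors)
    fixed <- fixed + cfg$afc_class_effects[cls]
  e <- stats::rnorm(nr, 0, sqrt(cfg$sigma2_e))
  y <- fixed + u[cows] + hys_eff[hys_class] + e

  phen <- data.frame(animal = ped$id[cows], value = y,
                     hys = as.integer(hys_f),
                     F = ped$F[cows], age_last_calving = age_lc,
                     afc_class = cls, stringsAsFactors = FALSE)
  phen <- phen[order(phen$animal, phen$hys), , drop = FALSE]
  rownames(phen) <- NULL
  truth <- list(u = stats::setNames(u, ped$id), qtl = qtl,
                hys_effects = hys_eff,
                mu = cfg$mean_trait,
                beta = list(F = cfg$beta_F, age_last_calving = cfg$beta_age,
                            afc_class = cfg$afc_class_effects),
                sigma2_a = cfg$sigma2_a, sigma2_hys = cfg$sigma2_hys,
                sigma2_e = cfg$sigma2_e,
                h2 = cfg$sigma2_a / (cfg$sigma2_a + cfg$sigma2_hys + cfg$sigma2_e))
  list(phenotypes = phen, truth = truth)
}

#' Simulate a complete herd
#'
#' Pedigree, genotypes and phenotypes under one configuration; the
#' configuration seed fixes all randomness end-to-end.
#'
#' @param cfg [sim_config()].
#' @return list `ped`, `genotypes` (all animals, with `genotyped_ids`
#'   attribute), `phenotypes`, `truth`, `cfg`.
#' @export
simulate_herd <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(ped, g, cfg)
  list(ped = ped, genotypes = g, phenotypes = ph$phenotypes,
       truth = ph$truth, cfg = cfg)
}

#' Write simulated data as analysis fixtures
#'
#' Pedigree CSV, PLINK .ped/.map of the genotyped subset, phenotype CSV
#' and truth JSON. Files are byte-stable under a fixed configuration
#' seed.
#'
#' @param herd from [simulate_herd()].
#' @param out_dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_fixtures <- function(herd, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(pedigree = file.path(out_dir, "pedigree.csv"),
             ped = file.path(out_dir, "genotypes.ped"),
             map = file.path(out_dir, "genotypes.map"),
             phenotypes = file.path(out_dir, "phenotypes.csv"),
             truth = file.path(out_dir, "truth.json"))
  pd <- as.data.frame(herd$ped)
  pd$sire[is.na(pd$sire)] <- "0"; pd$dam[is.na(pd$dam)] <- "0"
  utils::write.csv(pd[, c("id", "sire", "dam", "sex", "generation", "recorded")],
                   paths["pedigree"], row.names = FALSE, quote = FALSE)
  gsub <- subset_genotypes(herd$genotypes, attr(herd$genotypes, "genotyped_ids"))
  write_plink_text(gsub, paths["ped"], paths["map"])
  utils::write.csv(herd$phenotypes, paths["phenotypes"], row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(u = as.list(herd$truth$u),
         qtl = herd$truth$qtl,
         hys_effects = herd$truth$hys_effects,
         mu = herd$truth$mu, h2 = herd$truth$h2,
         sigma2_a = herd$truth$sigma2_a, sigma2_hys = herd$truth$sigma2_hys,
         sigma2_e = herd$truth$sigma2_e),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
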