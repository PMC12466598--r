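# Shared fixture builders. Everything is generated in code under fixed
# seeds; no files ship with the package.

# random acyclic pedigree: founders first, every later animal gets two
# distinct earlier parents
rand_pedigree <- function(n, n_founders = max(3L, n %/% 5L), seed = 1) {
  set.seed(seed)
  id <- paste0("A", seq_len(n))
  sire <- dam <- rep("", n)
  for (i in (n_founders + 1L):n) {
    sire[i] <- id[sample.int(i - 1L, 1)]
    dam[i] <- id[sample.int(i - 1L, 1)]
    while (dam[i] == sire[i]) dam[i] <- id[sample.int(i - 1L, 1)]
  }
  as_pedigree_table(data.frame(animal = id, sire = sire, dam = dam,
                               stringsAsFactors = FALSE))
}

# full-sib mating pedigree: offspring of two full sibs has F = 0.25
fullsib_pedigree <- function() {
  as_pedigree_table(data.frame(
    animal = c("f1", "f2", "s1", "s2", "x"),
    sire = c("", "", "f1", "f1", "s1"),
    dam = c("", "", "f2", "f2", "s2"),
    stringsAsFactors = FALSE))
}

# genotypes with no missing calls, one chromosome unless stated
toy_genotypes <- function(n, m, seed = 1, chrom = rep("1", m),
                          pos = seq_len(m) * 1000L, p = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.9)
  d <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  rownames(d) <- paste0("A", seq_len(n))
  genotype_matrix(d, data.frame(snp = paste0("s", seq_len(m)),
                                chrom = chrom, pos = pos,
                                stringsAsFactors = FALSE))
}

# dense GLS oracle for the animal model: direct generalized least squares
# on V = Z K Z' s2a + W W' s2h + I s2e
gls_oracle <- function(y, X, Z, W, K, vc) {
  Z <- as.matrix(Z); W <- as.matrix(W)
  V <- vc$sigma2_a * Z %*% K %*% t(Z) +
    vc$sigma2_hys * tcrossprod(W) + diag(vc$sigma2_e, length(y))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  u <- vc$sigma2_a * K %*% t(Z) %*% Vi %*% r
  cc <- vc$sigma2_hys * t(W) %*% Vi %*% r
  list(b = drop(b), u = drop(u), c = drop(cc))
}

# tiny herd configuration used by several module tests; ... overrides
small_herd_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(trait_profile = "ACI", n_founders = 80L, founder_female_frac = 0.8,
         n_generations = 3L, n_sires = 6L, n_dams = 30L,
         offspring_per_dam = 2L, n_snps = 120L, n_chromosomes = 4L,
         chrom_length_bp = 1e7, n_hys_classes = 12L, seed = seed),
    list(...))
  do.call(sim_config, args)
}
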