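# Genotype i/o, the QC cascade, frequencies, centering, G, blending,
# tuning, and the single-step H-inverse.

write_ped_map <- function(lines_ped, map_df) {
  pedf <- tempfile(fileext = ".ped"); mapf <- tempfile(fileext = ".map")
  writeLines(lines_ped, pedf)
  write.table(map_df, mapf, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  c(ped = pedf, map = mapf)
}

test_that("PLINK text reading recodes alleles deterministically", {
  fp <- write_ped_map(
    c("F1 a1 0 0 0 -9 A A", "F1 a2 0 0 0 -9 A G"),
    data.frame("1", "snp1", 0, 100))
  g <- read_plink_text(fp["ped"], fp["map"])
  expect_equal(unname(g$dosage[, 1]), c(2L, 1L))
  expect_equal(g$counted_allele, "A")
  expect_equal(g$other_allele, "G")

  # missing genotype
  fp2 <- write_ped_map(
    c("F1 a1 0 0 0 -9 0 0 C C", "F1 a2 0 0 0 -9 T T C G"),
    data.frame(c("1", "1"), c("s1", "s2"), 0, c(10, 20)))
  g2 <- read_plink_text(fp2["ped"], fp2["map"])
  expect_true(is.na(g2$dosage["a1", "s1"]))
  expect_equal(unname(g2$dosage["a2", ]), c(2L, 1L))

  # ragged row and 3-allele SNP are rejected with context
  fp3 <- write_ped_map(c("F1 a1 0 0 0 -9 A A", "F1 a2 0 0 0 -9 A"),
                       data.frame("1", "snp1", 0, 100))
  expect_error(read_plink_text(fp3["ped"], fp3["map"]), "line 2")
  fp4 <- write_ped_map(c("F1 a1 0 0 0 -9 A C", "F1 a2 0 0 0 -9 G G"),
                       data.frame("1", "snp1", 0, 100))
  expect_error(read_plink_text(fp4["ped"], fp4["map"]), "allele")
})

# the reader's counted allele is "first symbol observed in the file",
# so a SNP whose first-listed animal is homozygous for the other allele
# comes back with flipped coding; genotypes are identical either way
expect_same_genotypes <- function(g2, g) {
  for (j in seq_len(ncol(g$dosage))) {
    if (identical(g2$counted_allele[j], g$counted_allele[j])) {
      expect_equal(unname(g2$dosage[, j]), unname(g$dosage[, j]))
    } else {
      expect_identical(g2$counted_allele[j], g$other_allele[j])
      expect_equal(unname(g2$dosage[, j]), unname(2L - g$dosage[, j]))
    }
  }
}

test_that("PLINK text i/o round-trips the genotypes and the bytes", {
  g <- toy_genotypes(3, 3, seed = 4)
  g$dosage[2, 1] <- NA # include a missing call
  g$counted_allele <- c("A", "C", "G"); g$other_allele <- c("T", "G", "A")
  pedf <- tempfile(fileext = ".ped"); mapf <- tempfile(fileext = ".map")
  write_plink_text(g, pedf, mapf)
  g2 <- read_plink_text(pedf, mapf)
  expect_same_genotypes(g2, g)
  expect_equal(g2$map, g$map)
  expect_equal(rownames(g2$dosage), rownames(g$dosage))
  # writing the re-read object reproduces the files byte for byte
  pedf2 <- tempfile(); mapf2 <- tempfile()
  write_plink_text(g2, pedf2, mapf2)
  expect_identical(readLines(pedf2), readLines(pedf))
  expect_identical(readLines(mapf2), readLines(mapf))
})

test_that("the QC cascade drops non-autosomes, low-call individuals and low-MAF SNPs in order", {
  # constructed fixture: 12 SNPs of which 2 non-autosomal; 1 individual
  # with half its calls missing; exactly 3 autosomal SNPs pushed below
  # MAF 0.01 among the surviving individuals
  set.seed(1)
  n <- 60
  d <- matrix(rbinom(n * 12, 2L, 0.5), n, 12)
  rownames(d) <- paste0("A", seq_len(n))
  map <- data.frame(snp = paste0("s", 1:12),
                    chrom = c(rep("1", 5), "X", rep("2", 5), "30"),
                    pos = rep(1:6 * 1e5, 2))
  d[, map$snp %in% c("s2", "s8", "s11")] <- 0L # monomorphic -> MAF 0
  d[1, map$chrom %in% as.character(1:29)][seq_len(5)] <- NA # call rate 5/10
  g <- genotype_matrix(d, map)
  qc <- qc_filter(g, maf_min = 0.01, ind_callrate_min = 0.90)
  expect_equal(qc$report$stage,
               c("non_autosomal_snp", "individual_call_rate", "low_maf_snp"))
  expect_equal(qc$report$removed, c(2L, 1L, 3L))
  expect_equal(qc$report$snps_remaining, c(10L, 10L, 7L))
  expect_equal(qc$report$animals_remaining, c(60L, 59L, 59L))
  expect_false("A1" %in% rownames(qc$genotypes$dosage))
  expect_true(all(qc$genotypes$map$chrom %in% as.character(1:29)))

  # an all-monomorphic panel errors rather than returning nothing
  mono <- genotype_matrix(matrix(2L, 4, 2,
                                 dimnames = list(paste0("A", 1:4), NULL)),
                          data.frame(snp = c("a", "b"), chrom = "1",
                                     pos = c(1, 2)))
  expect_error(qc_filter(mono), "MAF")
})

test_that("allele frequencies match the brute-force per-column loop", {
  g1 <- genotype_matrix(matrix(c(0L, 1L, 2L), 3, 1,
                               dimnames = list(paste0("A", 1:3), NULL)),
                        data.frame(snp = "s", chrom = "1", pos = 1))
  f1 <- allele_frequencies(g1)
  expect_equal(f1$p, c(s = 0.5))
  expect_equal(f1$two_pq_sum, 0.5)

  g2 <- genotype_matrix(matrix(c(2L, 2L, NA), 3, 1,
                               dimnames = list(paste0("A", 1:3), NULL)),
                        data.frame(snp = "s", chrom = "1", pos = 1))
  expect_equal(allele_frequencies(g2)$p, c(s = 1))

  g <- toy_genotypes(20, 50, seed = 6)
  g$dosage[sample(length(g$dosage), 40)] <- NA
  f <- allele_frequencies(g)
  loop <- vapply(seq_len(50), function(j) {
    x <- g$dosage[, j]
    sum(x, na.rm = TRUE) / (2 * sum(!is.na(x)))
  }, numeric(1))
  expect_equal(unname(f$p), loop)
  expect_true(all(f$maf <= 0.5))
  # folded frequencies never exceed 0.5
  expect_true(all(allele_frequencies(g, fold = TRUE)$p <= 0.5))
})

test_that("centering subtracts 2p and imputes missing to exactly zero", {
  g <- genotype_matrix(matrix(c(0L, 1L, 2L, 2L, NA, 0L), 3, 2,
                              dimnames = list(paste0("A", 1:3), NULL)),
                       data.frame(snp = c("s1", "s2"), chrom = "1",
                                  pos = c(1, 2)))
  f <- allele_frequencies(g)
  Z <- center_dosages(g, f)
  expect_equal(unname(Z[, 1]), c(-1, 0, 1))
  expect_equal(mean(Z[, 1]), 0) # no missing -> exact zero column mean
  expect_identical(Z[2, 2], 0) # imputation contract
})

test_that("G matches hand arithmetic, ignores unit weights, and scales right under HW", {
  # 1 SNP, dosages 0/2: Z = (-1, 1), divisor 2*0.5*0.5 = 0.5
  g <- genotype_matrix(matrix(c(0L, 2L), 2, 1,
                              dimnames = list(c("A1", "A2"), NULL)),
                       data.frame(snp = "s", chrom = "1", pos = 1))
  f <- allele_frequencies(g)
  Z <- center_dosages(g, f)
  G <- build_G(Z, f)
  expect_equal(unclass(G), matrix(c(2, -2, -2, 2), 2),
               ignore_attr = TRUE)

  gg <- toy_genotypes(40, 60, seed = 7)
  ff <- allele_frequencies(gg)
  ZZ <- center_dosages(gg, ff)
  expect_equal(unclass(build_G(ZZ, ff, weights = rep(1, 60))),
               unclass(build_G(ZZ, ff)), ignore_attr = TRUE,
               tolerance = 1e-12)

  # Hardy-Weinberg simulation: mean diagonal ~ 1
  hw <- toy_genotypes(500, 800, seed = 8)
  fhw <- allele_frequencies(hw)
  Ghw <- build_G(center_dosages(hw, fhw), fhw)
  expect_lt(abs(mean(diag(Ghw)) - 1), 0.05)

  # relabeling invariance: permuting animals permutes G identically
  perm <- sample(40)
  Gp <- build_G(ZZ[perm, ], ff)
  expect_equal(unclass(Gp), unclass(build_G(ZZ, ff))[perm, perm],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("blending restores positive definiteness and tuning matches A22 means", {
  ped <- rand_pedigree(30, seed = 12)
  gids <- ped$id[11:30]
  A22 <- extract_A22(ped, gids)

  # duplicate animals make G singular; a 5% pedigree admixture fixes it
  g <- toy_genotypes(19, 50, seed = 13)
  d <- rbind(g$dosage, A20 = g$dosage[1, ])[seq_len(20), ]
  rownames(d) <- gids
  gdup <- genotype_matrix(d, g$map)
  f <- allele_frequencies(gdup)
  G <- build_G(center_dosages(gdup, f), f)
  expect_lt(min(eigen(unclass(G), symmetric = TRUE)$values), 1e-10)
  Gb <- blend_G(G, A22, 0.05)
  expect_gt(min(eigen(unclass(Gb), symmetric = TRUE)$values), 0)

  expect_identical(blend_G(G, A22, 0), G)
  expect_equal(unclass(blend_G(G, A22, 1)), unclass(A22), ignore_attr = TRUE)

  Gt <- tune_G(G, A22)
  expect_equal(mean(diag(Gt)), mean(diag(A22)), tolerance = 1e-12)
  offd <- function(M) (sum(M) - sum(diag(M))) / (nrow(M) * (nrow(M) - 1))
  expect_equal(offd(unclass(Gt)), offd(unclass(A22)), tolerance = 1e-12)
})

test_that("H-inverse reduces to A-inverse without genomic information", {
  ped <- rand_pedigree(25, seed = 14)
  Ainv <- build_A_inverse(ped)
  H0 <- build_H_inverse(Ainv, matrix(0, 0, 0), matrix(0, 0, 0), integer(0))
  expect_equal(as.matrix(H0), as.matrix(Ainv), ignore_attr = TRUE)

  gids <- ped$id[c(3, 9, 17, 21, 25)]
  A22 <- extract_A22(ped, gids)
  Hsame <- build_H_inverse(Ainv, A22, A22, match(gids, ped$id))
  expect_equal(as.matrix(Hsame), as.matrix(Ainv), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("H-inverse equals the dense inverse of the composite H", {
  ped <- rand_pedigree(40, seed = 15)
  A <- unclass(build_A_tabular(ped))
  gi <- sort(sample(40, 15))
  gids <- ped$id[gi]
  A22 <- A[gi, gi]
  set.seed(16)
  E <- matrix(rnorm(225, 0, 0.05), 15); E <- (E + t(E)) / 2
  G <- A22 + E + diag(0.1, 15)
  Hinv <- build_H_inverse(build_A_inverse(ped), A22, G, gi)

  ng <- setdiff(1:40, gi)
  A22i <- solve(A22)
  H <- A
  H[gi, gi] <- G
  H[ng, gi] <- A[ng, gi] %*% A22i %*% G
  H[gi, ng] <- t(H[ng, gi])
  H[ng, ng] <- A[ng, ng] +
    A[ng, gi] %*% A22i %*% (G - A22) %*% A22i %*% A[gi, ng]
  expect_lt(max(abs(solve(H) - as.matrix(Hinv))), 1e-10)

  # correction block is zero outside the genotyped sub-block
  diffm <- as.matrix(Hinv) - as.matrix(build_A_inverse(ped))
  expect_equal(max(abs(diffm[ng, ])), 0)
  expect_equal(max(abs(diffm[, ng])), 0)

  # a truly singular G directs the user to blending
  Gs <- G; Gs[1, ] <- Gs[2, ]; Gs[, 1] <- Gs[, 2]
  expect_error(build_H_inverse(build_A_inverse(ped), A22, Gs, gi), "blend")
})
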