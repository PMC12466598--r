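# Genotype handling: PLINK text i/o, the QC cascade (autosomes ->
# individual call rate -> MAF), allele frequencies, centered dosages,
# VanRaden G / weighted G*, blending, and the single-step H-inverse.

#' Construct a genotype matrix object
#'
#' @param dosage integer matrix, animals x SNPs, entries in `{0, 1, 2, NA}`
#'   counting copies of the counted allele; rownames are animal ids.
#' @param map data.frame with columns `snp`, `chrom`, `pos` (1-based bp).
#'   SNPs are sorted by chromosome then position, and the dosage columns
#'   reordered to match.
#' @param counted_allele,other_allele per-SNP allele symbols.
#' @return a `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosage, map,
                            counted_allele = rep("A", ncol(dosage)),
                            other_allele = rep("B", ncol(dosage))) {
  stopifnot(is.matrix(dosage), nrow(map) == ncol(dosage),
            all(c("snp", "chrom", "pos") %in% names(map)))
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0/1/2 or missing")
  map$chrom <- as.character(map$chrom)
  ord <- order(chrom_rank(map$chrom), map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  if (anyDuplicated(map[c("chrom", "pos")]))
    stop("duplicated map positions within a chromosome")
  dosage <- dosage[, ord, drop = FALSE]
  colnames(dosage) <- map$snp
  structure(list(dosage = dosage, map = map,
                 counted_allele = counted_allele[ord],
                 other_allele = other_allele[ord]),
            class = "genotype_matrix")
}

# numeric chromosomes first in numeric order, labels after
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  ifelse(is.na(num), 1e6 + as.numeric(factor(chrom)), num)
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotypes: %d animals x %d SNPs on %d chromosome(s), %.2f%% missing>\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

animal_ids <- function(g) rownames(g$dosage)

#' Subset a genotype matrix by animal ids
#' @param g `genotype_matrix`.
#' @param ids animal ids to keep, in the requested order.
#' @return subsetted `genotype_matrix`.
#' @export
subset_genotypes <- function(g, ids) {
  idx <- match(ids, animal_ids(g))
  if (anyNA(idx))
    stop("unknown animal id(s): ", paste(head(ids[is.na(idx)], 5), collapse = ", "))
  g$dosage <- g$dosage[idx, , drop = FALSE]
  g
}

#' Read PLINK text genotypes (.ped/.map)
#'
#' The counted allele of each SNP is the first non-missing allele symbol
#' observed in file order, which makes the coding deterministic for a given
#' file. `0 0` genotypes become missing dosages.
#'
#' @param ped_path 6-column + 2-per-SNP PLINK .ped text file.
#' @param map_path 4-column .map file (chrom, snp, cM, bp).
#' @return a [genotype_matrix()].
#' @export
read_plink_text <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) != 4L) stop("expected a 4-column .map file")
  map <- data.frame(snp = map[[2]], chrom = map[[1]],
                    pos = as.integer(map[[4]]))
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(toks)
  bad <- which(nf != 6L + 2L * m)
  if (length(bad))
    stop("ragged .ped row(s) at line ", bad[1], ": expected ", 6L + 2L * m,
         " fields, found ", nf[bad[1]])
  tk <- do.call(rbind, toks)
  ids <- tk[, 2]
  n <- length(ids)
  dosage <- matrix(NA_integer_, n, m)
  counted <- other <- character(m)
  for (j in seq_len(m)) {
    a1 <- tk[, 5L + 2L * j]
    a2 <- tk[, 6L + 2L * j]
    miss <- a1 == "0" | a2 == "0"
    seen <- c(rbind(a1, a2))
    seen <- seen[seen != "0"]
    alleles <- unique(seen)
    if (length(alleles) > 2L)
      stop("more than two allele symbols for SNP ", map$snp[j], " (",
           paste(alleles, collapse = ","), ")")
    if (!length(alleles)) alleles <- "A"
    counted[j] <- alleles[1]
    other[j] <- if (length(alleles) == 2L) alleles[2] else "0"
    dosage[, j] <- (a1 == counted[j]) + (a2 == counted[j])
    dosage[miss, j] <- NA_integer_
  }
  rownames(dosage) <- ids
  genotype_matrix(dosage, map, counted, other)
}

#' Write PLINK text genotypes (.ped/.map)
#'
#' Inverse of [read_plink_text()]; the pair round-trips bit-identically.
#'
#' @param g `genotype_matrix`.
#' @param ped_path,map_path output paths.
#' @return `ped_path`, invisibly.
#' @export
write_plink_text <- function(g, ped_path, map_path) {
  map <- g$map
  utils::write.table(data.frame(map$chrom, map$snp, 0L, map$pos),
                     map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  n <- nrow(g$dosage); m <- ncol(g$dosage)
  al <- matrix("0", n, 2L * m)
  for (j in seq_len(m)) {
    dj <- g$dosage[, j]
    a <- ifelse(is.na(dj), "0", ifelse(dj >= 1L, g$counted_allele[j], g$other_allele[j]))
    b <- ifelse(is.na(dj), "0", ifelse(dj == 2L, g$counted_allele[j], g$other_allele[j]))
    # heterozygotes in canonical symbol order, so the written file does
    # not depend on which allele the in-memory object happens to count
    het <- !is.na(dj) & dj == 1L
    a[het] <- pmin(g$counted_allele[j], g$other_allele[j])
    b[het] <- pmax(g$counted_allele[j], g$other_allele[j])
    al[, 2L * j - 1L] <- a
    al[, 2L * j] <- b
  }
  fam <- cbind(rownames(g$dosage), rownames(g$dosage), "0", "0", "0", "-9")
  utils::write.table(cbind(fam, al), ped_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(ped_path)
}

#' Read a PLINK .raw additive dosage file
#'
#' Header `FID IID PAT MAT SEX PHENOTYPE <snp>_<allele> ...` with 0/1/2/NA
#' dosages, as produced by `plink --recode A`. Map positions are not part
#' of the format, so they must be supplied.
#'
#' @param raw_path .raw file.
#' @param map data.frame `snp`, `chrom`, `pos` matching the SNP columns.
#' @return a [genotype_matrix()].
#' @export
read_plink_raw <- function(raw_path, map) {
  df <- utils::read.table(raw_path, header = TRUE, check.names = FALSE)
  dos <- as.matrix(df[, -(1:6), drop = FALSE])
  counted <- sub(".*_", "", colnames(dos))
  snp <- sub("_[^_]*$", "", colnames(dos))
  storage.mode(dos) <- "integer"
  rownames(dos) <- as.character(df$IID)
  colnames(dos) <- snp
  map <- map[match(snp, map$snp), , drop = FALSE]
  genotype_matrix(dos, map, counted_allele = counted,
                  other_allele = rep("0", length(snp)))
}

#' Quality-control cascade for genotypes
#'
#' Applies, in order: (1) keep autosomal SNPs only; (2) drop individuals
#' whose call rate over the remaining SNPs is below `ind_callrate_min`;
#' (3) recompute allele frequencies on the remaining individuals and drop
#' SNPs with minor allele frequency below `maf_min` (monomorphic SNPs have
#' MAF 0 and are dropped here).
#'
#' @param g `genotype_matrix`.
#' @param maf_min minimum minor allele frequency (default 0.01; strict `<`
#'   removal).
#' @param ind_callrate_min minimum individual call rate (default 0.90).
#' @param autosomes chromosome labels considered autosomal (default 1..29,
#'   the bovine autosomes).
#' @return list with the filtered `genotypes` and a `report` data.frame of
#'   per-stage drop counts.
#' @export
qc_filter <- function(g, maf_min = 0.01, ind_callrate_min = 0.90,
                      autosomes = as.character(1:29)) {
  stopifnot(inherits(g, "genotype_matrix"))
  autosomes <- as.character(autosomes)
  keep_snp <- g$map$chrom %in% autosomes
  n_nonauto <- sum(!keep_snp)
  g1 <- keep_snps(g, keep_snp)
  if (ncol(g1$dosage) == 0L) stop("no autosomal SNPs remain after QC")

  callrate <- rowMeans(!is.na(g1$dosage))
  keep_ind <- callrate >= ind_callrate_min
  n_lowcall <- sum(!keep_ind)
  g2 <- g1
  g2$dosage <- g2$dosage[keep_ind, , drop = FALSE]
  if (nrow(g2$dosage) == 0L) stop("no individuals remain after call-rate QC")

  p <- colMeans(g2$dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep_maf <- !is.na(maf) & maf >= maf_min
  n_lowmaf <- sum(!keep_maf)
  g3 <- keep_snps(g2, keep_maf)
  if (ncol(g3$dosage) == 0L) stop("all SNPs removed by the MAF filter")

  report <- data.frame(
    stage = c("non_autosomal_snp", "individual_call_rate", "low_maf_snp"),
    removed = c(n_nonauto, n_lowcall, n_lowmaf),
    snps_remaining = c(ncol(g1$dosage), ncol(g2$dosage), ncol(g3$dosage)),
    animals_remaining = c(nrow(g1$dosage), nrow(g2$dosage), nrow(g3$dosage)))
  class(report) <- c("qc_report", "data.frame")
  list(genotypes = g3, report = report)
}

keep_snps <- function(g, keep) {
  g$dosage <- g$dosage[, keep, drop = FALSE]
  g$map <- g$map[keep, , drop = FALSE]
  rownames(g$map) <- NULL
  g$counted_allele <- g$counted_allele[keep]
  g$other_allele <- g$other_allele[keep]
  g
}

#' Observed allele frequencies of the counted allele
#'
#' `p` is computed per SNP as `mean(dosage)/2` over non-missing calls in
#' the genotyped set. The centering and the VanRaden divisor use this
#' counted-allele frequency; `fold = TRUE` replaces `p` by the folded MAF
#' (a sensitivity switch only -- folding flips centering signs for SNPs
#' whose counted allele is the major one).
#'
#' @param g post-QC `genotype_matrix`.
#' @param fold use folded minor allele frequencies instead.
#' @return list with `p`, `maf` and `two_pq_sum` (`sum(2 p (1-p))`).
#' @export
allele_frequencies <- function(g, fold = FALSE) {
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  if (fold) p <- maf
  structure(list(p = p, maf = maf, two_pq_sum = sum(2 * p * (1 - p))),
            class = "allele_frequencies")
}

#' Centered dosage matrix Z
#'
#' `Z_ij = dosage_ij - 2 p_j`; missing dosages are mean-imputed, i.e. the
#' centered cell is exactly 0.
#'
#' @param g post-QC `genotype_matrix`.
#' @param f frequencies from [allele_frequencies()] on the same matrix.
#' @return dense numeric matrix with the genotype dimnames.
#' @export
center_dosages <- function(g, f) {
  Z <- sweep(`storage.mode<-`(g$dosage, "double"), 2, 2 * f$p, `-`)
  Z[is.na(Z)] <- 0
  Z
}

#' Per-SNP variance weights (diagonal of D)
#'
#' Weights are normalized to mean 1 (`trace(D) = N`), so weighted and
#' unweighted genomic relationship matrices stay on the same scale.
#'
#' @param d nonnegative per-SNP weights.
#' @param iteration which weighting iteration produced them.
#' @return `snp_weights` object (numeric vector with attributes).
#' @export
snp_weights <- function(d, iteration = 0L) {
  stopifnot(all(d >= 0), any(d > 0))
  d <- d / mean(d)
  structure(d, iteration = as.integer(iteration), class = "snp_weights")
}

#' VanRaden genomic relationship matrix (optionally weighted)
#'
#' `G = Z D Z' / sum(2 p_i (1 - p_i))` with `D = I` for the plain matrix
#' and `D = diag(d)` for the weighted `G*`. Because weights are normalized
#' to mean 1 upstream, rescaling them by a constant has no effect; with
#' the divisor held fixed, unnormalized weights would scale G linearly.
#'
#' @param Z centered dosages from [center_dosages()].
#' @param f matching [allele_frequencies()].
#' @param weights optional [snp_weights()] (or numeric vector, normalized
#'   here).
#' @return dense `relationship_matrix` of kind `"G"` or `"G_weighted"`.
#' @export
build_G <- function(Z, f, weights = NULL) {
  stopifnot(f$two_pq_sum > 0)
  if (is.null(weights)) {
    G <- tcrossprod(Z) / f$two_pq_sum
    kind <- "G"
  } else {
    if (!inherits(weights, "snp_weights")) weights <- snp_weights(weights)
    G <- tcrossprod(sweep(Z, 2, sqrt(as.numeric(weights)), `*`)) / f$two_pq_sum
    kind <- "G_weighted"
  }
  new_relationship_matrix(G, rownames(Z), kind)
}

#' Rescale G to the pedigree base (match A22 means)
#'
#' VanRaden G centered at the observed allele frequencies of a related
#' genotyped sample is expressed relative to that sample's own average
#' relatedness, not the pedigree base: its mean off-diagonal is ~0 while
#' `A22`'s is positive. The standard compatibility adjustment solves
#' `a + b * mean(diag(G)) = mean(diag(A22))` and
#' `a + b * mean(offdiag(G)) = mean(offdiag(A22))` and returns
#' `a + b * G`, so additive variance is expressed on the same base as the
#' pedigree. Routine genomic-evaluation software applies this silently;
#' it is the default here too (see [fit_ssgreml()]).
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationships of the same animals, same order.
#' @return adjusted `relationship_matrix`, kind preserved.
#' @export
tune_G <- function(G, A22) {
  stopifnot(all(dim(G) == dim(A22)))
  Gm <- as.matrix(G); Am <- as.matrix(A22)
  n <- nrow(Gm)
  mdG <- mean(diag(Gm)); mdA <- mean(diag(Am))
  moG <- (sum(Gm) - sum(diag(Gm))) / (n * (n - 1))
  moA <- (sum(Am) - sum(diag(Am))) / (n * (n - 1))
  b <- (mdA - moA) / (mdG - moG)
  a <- mdA - b * mdG
  new_relationship_matrix(a + b * Gm, rownames(G), rel_kind(G) %||% "G")
}

#' Blend G with A22 for invertibility
#'
#' `(1 - alpha) G + alpha A22`. A small pedigree admixture guarantees a
#' positive-definite genomic matrix when G is singular (more animals than
#' effectively independent markers, duplicate genotypes).
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationships of the same animals, same order.
#' @param alpha blending fraction in `[0, 1]` (default 0.05).
#' @return blended `relationship_matrix` (kind preserved from `G` when
#'   `alpha = 0`).
#' @export
blend_G <- function(G, A22, alpha = 0.05) {
  stopifnot(alpha >= 0, alpha <= 1, all(dim(G) == dim(A22)))
  if (alpha == 0) return(G)
  out <- (1 - alpha) * as.matrix(G) + alpha * as.matrix(A22)
  new_relationship_matrix(out, rownames(G), rel_kind(G) %||% "G")
}

#' Single-step H-matrix inverse
#'
#' `H^{-1} = A^{-1} + [0 0; 0 G^{-1} - A22^{-1}]`, the correction block
#' scattered onto the genotyped rows/columns of the pedigree. The result
#' is a sparse symmetric matrix (the genotyped block is dense inside it)
#' directly usable in the mixed-model equations.
#'
#' @param A_inv sparse A-inverse from [build_A_inverse()].
#' @param A22 genotyped-block pedigree relationships.
#' @param G_blended (blended) genomic relationship matrix.
#' @param genotyped_index positions (codes) of the genotyped animals in
#'   pedigree order, aligned with the rows of `G_blended`/`A22`.
#' @return sparse symmetric `relationship_matrix` of kind `"H_inverse"`
#'   with attribute `genotyped_index`.
#' @export
build_H_inverse <- function(A_inv, A22, G_blended, genotyped_index) {
  ng <- length(genotyped_index)
  stopifnot(nrow(A22) == ng, nrow(G_blended) == ng)
  if (ng == 0L) {
    out <- new_relationship_matrix(A_inv, rownames(A_inv), "H_inverse")
    attr(out, "genotyped_index") <- integer(0)
    return(out)
  }
  Ginv <- tryCatch(chol2inv(chol(as.matrix(G_blended))), error = function(e)
    stop("G is singular; blend it with A22 first (see blend_G())"))
  A22inv <- chol2inv(chol(as.matrix(A22)))
  corr <- Ginv - A22inv
  S <- Matrix::sparseMatrix(i = rep(genotyped_index, times = ng),
                            j = rep(genotyped_index, each = ng),
                            x = as.vector(corr), dims = dim(A_inv))
  H <- Matrix::forceSymmetric(Matrix::drop0((A_inv + S) * 1.0), uplo = "U")
  out <- new_relationship_matrix(H, rownames(A_inv), "H_inverse")
  attr(out, "genotyped_index") <- genotyped_index
  out
}
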