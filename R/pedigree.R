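# Pedigree handling: parsing and topological ordering, Meuwissen-Luo
# inbreeding, the dense tabular numerator relationship matrix A (test
# oracle), Henderson's sparse A-inverse, and indirect extraction of the
# genotyped block A22 without ever forming the full dense A.

#' Build a validated, topologically sorted pedigree table
#'
#' Animals are stored in an order where every known parent precedes its
#' offspring; external (alphanumeric) ids are mapped once to integer codes
#' `1..n` in that order, and all relationship matrices are indexed by code.
#' Parents that are referenced but have no row of their own are added as
#' founders.
#'
#' @param df data.frame whose first three columns (or the columns named by
#'   `id_columns`) are animal, sire and dam ids. Any further columns
#'   (e.g. `birth_year`, `herd`, `sex`, `generation`) are carried through.
#' @param id_columns names of the animal/sire/dam columns.
#' @param missing_codes values treated as "parent unknown".
#' @return A `pedigree_table`: a data.frame with columns `id`, `sire`,
#'   `dam` (character, `NA` = unknown), integer codes `sire_code`,
#'   `dam_code` (0 = unknown), an `F` column of inbreeding coefficients
#'   (`NA` until [compute_inbreeding()] is called), and any carried
#'   metadata. Row order is the topological order; the row number is the
#'   animal's code.
#' @seealso [read_pedigree()], [compute_inbreeding()]
#' @export
as_pedigree_table <- function(df, id_columns = NULL,
                              missing_codes = c("", "0", "NA")) {
  stopifnot(is.data.frame(df), ncol(df) >= 3L)
  if (is.null(id_columns)) id_columns <- names(df)[1:3]
  stopifnot(all(id_columns %in% names(df)))
  id   <- trimws(as.character(df[[id_columns[1]]]))
  sire <- trimws(as.character(df[[id_columns[2]]]))
  dam  <- trimws(as.character(df[[id_columns[3]]]))
  sire[sire %in% missing_codes | is.na(sire)] <- NA_character_
  dam[dam %in% missing_codes | is.na(dam)] <- NA_character_
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate animal id(s) in pedigree: ", paste(head(dup, 5), collapse = ", "))
  }
  extra <- df[, setdiff(names(df), id_columns), drop = FALSE]

  # parents referenced but absent become founders (prepended)
  ghosts <- setdiff(c(sire, dam), c(id, NA_character_))
  if (length(ghosts)) {
    id <- c(ghosts, id)
    sire <- c(rep(NA_character_, length(ghosts)), sire)
    dam <- c(rep(NA_character_, length(ghosts)), dam)
    if (ncol(extra)) {
      pad <- extra[rep(NA_integer_, length(ghosts)), , drop = FALSE]
      extra <- rbind(pad, extra)
    }
  }
  n <- length(id)
  s_idx <- match(sire, id); s_idx[is.na(s_idx)] <- 0L
  d_idx <- match(dam, id); d_idx[is.na(d_idx)] <- 0L

  ord <- topo_order(id, s_idx, d_idx)
  id <- id[ord]; sire <- sire[ord]; dam <- dam[ord]
  if (ncol(extra)) extra <- extra[ord, , drop = FALSE]
  sc <- match(sire, id); sc[is.na(sc)] <- 0L
  dc <- match(dam, id); dc[is.na(dc)] <- 0L

  out <- data.frame(id = id, sire = sire, dam = dam,
                    sire_code = sc, dam_code = dc, F = NA_real_,
                    stringsAsFactors = FALSE)
  if (ncol(extra)) out <- cbind(out, extra)
  rownames(out) <- NULL
  class(out) <- c("pedigree_table", "data.frame")
  out
}

# Kahn-style stable topological sort; reports one cycle on failure.
topo_order <- function(id, s_idx, d_idx) {
  n <- length(id)
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ok_s <- s_idx == 0L | placed[pmax(s_idx, 1L)]
    ok_d <- d_idx == 0L | placed[pmax(d_idx, 1L)]
    ready <- which(!placed & ok_s & ok_d)
    if (!length(ready)) {
      if (all(placed)) break
      # walk parent pointers among the unplaced animals to exhibit a cycle
      start <- which(!placed)[1]
      path <- integer(0); cur <- start
      while (!cur %in% path) {
        path <- c(path, cur)
        nxt <- c(s_idx[cur], d_idx[cur])
        nxt <- nxt[nxt > 0L & !placed[pmax(nxt, 1L)]]
        cur <- nxt[1]
      }
      cyc <- c(path[which(path == cur):length(path)], cur)
      stop("pedigree cycle detected: ", paste(id[cyc], collapse = " -> "))
    }
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  ord
}

#' Read a pedigree CSV
#'
#' Expects a header row and columns `animal,sire,dam[,birth_year,herd,...]`
#' (names configurable). Missing parents may be encoded as an empty field,
#' `0` or `NA`.
#'
#' @param path CSV file.
#' @inheritParams as_pedigree_table
#' @return A [as_pedigree_table()] pedigree.
#' @export
read_pedigree <- function(path, id_columns = NULL,
                          missing_codes = c("", "0", "NA")) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  as_pedigree_table(df, id_columns = id_columns, missing_codes = missing_codes)
}

#' @method print pedigree_table
#' @export
print.pedigree_table <- function(x, ...) {
  cat(sprintf("<pedigree: %d animals, %d founders%s>\n", nrow(x),
              sum(x$sire_code == 0L & x$dam_code == 0L),
              if (all(is.na(x$F))) "" else
                sprintf(", mean F = %.4f", mean(x$F))))
  NextMethod()
}

stopifnot_pedigree <- function(ped) {
  if (!inherits(ped, "pedigree_table"))
    stop("expected a sorted `pedigree_table`; build one with as_pedigree_table()/read_pedigree()")
  invisible(ped)
}

#' Meuwissen-Luo inbreeding coefficients
#'
#' Fills the `F` column using the recursive algorithm of Meuwissen and Luo,
#' which accumulates each animal's ancestor contributions in a single
#' descending pass per animal. Founders get `F = 0`; the computation is
#' idempotent.
#'
#' @param ped a sorted `pedigree_table`.
#' @return The pedigree with `F` filled.
#' @export
compute_inbreeding <- function(ped) {
  stopifnot_pedigree(ped)
  ped$F <- ml_inbreeding(ped$sire_code, ped$dam_code)
  ped
}

has_inbreeding <- function(ped) !anyNA(ped$F)

# Mendelian sampling variances d_i used by both A-inverse and the
# indirect (Colleau) A-column solves.
mendelian_d <- function(ped) {
  if (!has_inbreeding(ped)) ped <- compute_inbreeding(ped)
  s <- ped$sire_code; d <- ped$dam_code
  Fs <- ifelse(s > 0L, ped$F[pmax(s, 1L)], 0)
  Fd <- ifelse(d > 0L, ped$F[pmax(d, 1L)], 0)
  both <- s > 0L & d > 0L
  one <- xor(s > 0L, d > 0L)
  out <- rep(1, nrow(ped))
  out[both] <- 0.5 - 0.25 * (Fs[both] + Fd[both])
  out[one] <- 0.75 - 0.25 * (Fs[one] + Fd[one])
  out
}

#' Dense tabular numerator relationship matrix (oracle)
#'
#' Classic recursion `a_ij = (a_{j,s(i)} + a_{j,d(i)})/2`,
#' `a_ii = 1 + a_{s(i),d(i)}/2`. Quadratic in memory, so intended for
#' small pedigrees only; the capped size keeps it honest as a test oracle
#' for the sparse machinery.
#'
#' @param ped sorted `pedigree_table`.
#' @param cap maximum pedigree size for the dense recursion.
#' @return dense `relationship_matrix` of kind `"A"` with `diag(A) = 1 + F`.
#' @export
build_A_tabular <- function(ped, cap = 2000L) {
  stopifnot_pedigree(ped)
  n <- nrow(ped)
  if (n > cap)
    stop("pedigree has ", n, " animals, above the dense-oracle cap (", cap,
         "); use build_A_inverse()/extract_A22() instead")
  s <- ped$sire_code; d <- ped$dam_code
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s[i]) row <- row + 0.5 * A[s[i], j]
      if (d[i]) row <- row + 0.5 * A[d[i], j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (s[i] && d[i]) 0.5 * A[s[i], d[i]] else 0
  }
  new_relationship_matrix(A, ped$id, "A")
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' `1/d_i` on its diagonal, `-0.5/d_i` on the (animal, parent) pattern and
#' `0.25/d_i` among its known parents, with Mendelian sampling variance
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (one-parent and founder cases reduce to
#' `0.75 - 0.25 F` and `1`).
#'
#' @param ped sorted `pedigree_table` (inbreeding is computed if absent).
#' @return sparse symmetric `relationship_matrix` of kind `"A_inverse"`.
#' @export
build_A_inverse <- function(ped) {
  stopifnot_pedigree(ped)
  if (!has_inbreeding(ped)) ped <- compute_inbreeding(ped)
  n <- nrow(ped)
  s <- ped$sire_code; d <- ped$dam_code
  w <- 1 / mendelian_d(ped)
  i0 <- seq_len(n)
  ii <- i0; jj <- i0; xx <- w
  hs <- which(s > 0L)
  if (length(hs)) {
    ii <- c(ii, hs, s[hs], s[hs])
    jj <- c(jj, s[hs], hs, s[hs])
    xx <- c(xx, -0.5 * w[hs], -0.5 * w[hs], 0.25 * w[hs])
  }
  hd <- which(d > 0L)
  if (length(hd)) {
    ii <- c(ii, hd, d[hd], d[hd])
    jj <- c(jj, d[hd], hd, d[hd])
    xx <- c(xx, -0.5 * w[hd], -0.5 * w[hd], 0.25 * w[hd])
  }
  hb <- which(s > 0L & d > 0L)
  if (length(hb)) {
    ii <- c(ii, s[hb], d[hb])
    jj <- c(jj, d[hb], s[hb])
    xx <- c(xx, 0.25 * w[hb], 0.25 * w[hb])
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Ainv <- Matrix::forceSymmetric(Ainv, uplo = "U")
  new_relationship_matrix(Ainv, ped$id, "A_inverse")
}

#' Columns of A by the indirect (Colleau) method
#'
#' Uses `A = (I - P)^{-1} D (I - P)^{-T}` where `P` holds 0.5 at the
#' (animal, known parent) positions and `D` the Mendelian sampling
#' variances, so a block of columns of `A` costs two sparse triangular
#' solves instead of the quadratic tabular recursion.
#'
#' @param ped sorted `pedigree_table`.
#' @param ids animal ids selecting the columns.
#' @return dense `n x length(ids)` matrix of the requested columns of A,
#'   rows in pedigree order.
#' @export
relationship_columns <- function(ped, ids) {
  stopifnot_pedigree(ped)
  codes <- match(ids, ped$id)
  if (anyNA(codes))
    stop("unknown animal id(s): ", paste(head(ids[is.na(codes)], 5), collapse = ", "))
  n <- nrow(ped)
  Dv <- mendelian_d(ped)
  s <- ped$sire_code; d <- ped$dam_code
  hs <- which(s > 0L); hd <- which(d > 0L)
  IP <- Matrix::sparseMatrix(i = c(seq_len(n), hs, hd),
                             j = c(seq_len(n), s[hs], d[hd]),
                             x = c(rep(1, n), rep(-0.5, length(hs)),
                                   rep(-0.5, length(hd))),
                             dims = c(n, n))
  IP <- tryCatch(as(IP, "triangularMatrix"), error = function(e) IP)
  V <- matrix(0, n, length(codes))
  V[cbind(codes, seq_along(codes))] <- 1
  X <- Matrix::solve(Matrix::t(IP), V)
  out <- Matrix::solve(IP, Dv * as.matrix(X))
  out <- as.matrix(out)
  dimnames(out) <- list(ped$id, ids)
  out
}

#' Pedigree relationship matrix of the genotyped animals (A22)
#'
#' Restriction of A to the genotyped subset, computed without forming the
#' full dense A (see [relationship_columns()]). Row/column order follows
#' `genotyped_ids`.
#'
#' @param ped sorted `pedigree_table`.
#' @param genotyped_ids ids of the genotyped animals (must be in the
#'   pedigree).
#' @return dense `relationship_matrix` of kind `"A22"`.
#' @export
extract_A22 <- function(ped, genotyped_ids) {
  cols <- relationship_columns(ped, genotyped_ids)
  codes <- match(genotyped_ids, ped$id)
  A22 <- cols[codes, , drop = FALSE]
  A22 <- (A22 + t(A22)) / 2
  new_relationship_matrix(A22, genotyped_ids, "A22")
}

#' Prune a pedigree to the ancestors of a keep set
#'
#' Optional reduction to the animals contributing to a set of
#' genotyped/phenotyped individuals. The default analysis uses the full
#' pedigree; pruning is provided for users with very deep herdbooks.
#'
#' @param ped sorted `pedigree_table`.
#' @param keep_ids ids whose ancestor closure is retained.
#' @return pruned, re-coded `pedigree_table`.
#' @export
prune_pedigree <- function(ped, keep_ids) {
  stopifnot_pedigree(ped)
  codes <- match(keep_ids, ped$id)
  if (anyNA(codes))
    stop("unknown animal id(s): ",
         paste(head(keep_ids[is.na(codes)], 5), collapse = ", "))
  keep <- logical(nrow(ped))
  keep[codes] <- TRUE
  # pedigree order guarantees parents precede offspring, so one reverse
  # sweep closes the ancestor set
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      if (ped$sire_code[i]) keep[ped$sire_code[i]] <- TRUE
      if (ped$dam_code[i]) keep[ped$dam_code[i]] <- TRUE
    }
  }
  sub <- as.data.frame(ped)[keep, c("id", "sire", "dam",
                                    setdiff(names(ped), c("id", "sire", "dam",
                                                          "sire_code", "dam_code", "F")))]
  as_pedigree_table(sub)
}
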