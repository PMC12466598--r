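# Weighted single-step GWAS: back-solving SNP effects from the GEBVs of
# the genotyped animals, per-SNP variances and weights, the iterative
# re-weighting loop, and the sliding 1-Mb window decomposition of
# additive genetic variance.

#' Back-solve SNP effects from genotyped-animal GEBVs
#'
#' `a_hat = D Z' (Z D Z')^{-1} u_g`. With `D = I` this is the plain
#' single-step back-solve; in the weighted iterations `D` holds the SNP
#' variance weights. Only genotyped animals enter (rows of `Z` aligned
#' with `u_g`). `Z D Z'` is singular whenever animals outnumber
#' effectively independent markers, so the scaled blended genomic matrix
#' (`G* . sum(2pq)`) is normally passed in its place.
#'
#' @param Z centered dosages of the genotyped animals.
#' @param weights [snp_weights()] or `NULL` for `D = I`.
#' @param u_g GEBVs of the genotyped animals, same row order as `Z`.
#' @param ZDZt optional replacement for `Z D Z'` (typically
#'   `G_blended * two_pq_sum`).
#' @return `snp_effects`: data.frame with `snp`, `a_hat` and a `var_u`
#'   column filled by [snp_variances()].
#' @export
backsolve_snp_effects <- function(Z, weights = NULL, u_g, ZDZt = NULL) {
  stopifnot(nrow(Z) == length(u_g))
  d <- if (is.null(weights)) rep(1, ncol(Z)) else as.numeric(weights)
  if (is.null(ZDZt)) ZDZt <- tcrossprod(sweep(Z, 2, sqrt(d), `*`))
  sol <- tryCatch(solve(as.matrix(ZDZt), u_g), error = function(e)
    stop("Z D Z' is singular; pass the blended genomic matrix (blend_G) as ZDZt"))
  a_hat <- d * drop(crossprod(Z, sol))
  out <- data.frame(snp = colnames(Z) %||% seq_len(ncol(Z)),
                    a_hat = a_hat, var_u = NA_real_)
  attr(out, "iteration") <- attr(weights, "iteration") %||% 0L
  class(out) <- c("snp_effects", "data.frame")
  out
}

#' Individual SNP-effect variances
#'
#' `var_u_i = 2 a_hat_i^2 p_i (1 - p_i)`; monomorphic SNPs (`p` 0 or 1)
#' get zero.
#'
#' @param effects `snp_effects` from [backsolve_snp_effects()].
#' @param f matching [allele_frequencies()].
#' @return `effects` with `var_u` filled.
#' @export
snp_variances <- function(effects, f) {
  stopifnot(nrow(effects) == length(f$p))
  effects$var_u <- 2 * effects$a_hat^2 * f$p * (1 - f$p)
  effects
}

#' SNP weights from effect variances
#'
#' `d_i` proportional to `var_u_i`, normalized to mean 1 so the weighted
#' genomic matrix keeps the scale of the unweighted one. An optional
#' ceiling caps individual weights after normalization.
#'
#' @param effects `snp_effects` with `var_u` filled.
#' @param ceiling optional maximum weight.
#' @return [snp_weights()] for the next iteration.
#' @export
update_weights <- function(effects, ceiling = NULL) {
  stopifnot(!anyNA(effects$var_u))
  d <- effects$var_u
  if (all(d == 0)) d <- rep(1, length(d))
  if (!is.null(ceiling)) d <- pmin(d / mean(d), ceiling)
  snp_weights(d, iteration = (attr(effects, "iteration") %||% 0L) + 1L)
}

#' Sliding 1-Mb SNP windows
#'
#' One window per SNP (the left anchor): all consecutive SNPs on the same
#' chromosome whose position satisfies `pos_k - pos_j < span_bp`. Windows
#' never cross chromosomes, so the window count equals the SNP count. The
#' reported coordinates are `[pos of first SNP, pos of first SNP + span)`.
#'
#' @param map data.frame `snp`, `chrom`, `pos` of the post-QC SNPs (sorted
#'   by chromosome and position).
#' @param span_bp window span in bp (default 1 Mb).
#' @return data.frame with one row per window: `chrom`, `start_bp`,
#'   `end_bp`, `first_snp`, `last_snp` (global SNP indices), `n_snps`.
#' @export
define_windows <- function(map, span_bp = 1e6) {
  stopifnot(all(c("chrom", "pos") %in% names(map)))
  out <- lapply(split(seq_len(nrow(map)), map$chrom), function(idx) {
    pos <- map$pos[idx]
    if (is.unsorted(pos, strictly = TRUE))
      stop("map positions must be strictly increasing within chromosome")
    last <- findInterval(pos + span_bp - 1, pos)
    data.frame(chrom = map$chrom[idx[1]], start_bp = pos,
               end_bp = pos + span_bp, first_snp = idx,
               last_snp = idx[last], n_snps = last - seq_along(idx) + 1L)
  })
  out <- do.call(rbind, out)
  out <- out[order(chrom_rank(out$chrom), out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage of additive genetic variance per window
#'
#' For window `i`, the genetic value of each genotyped animal is
#' `g = sum_{j in window} Z_j a_hat_j`; the window's share is
#' `Var(g) / sigma2_a x 100`. The empirical variance uses denominator `n`
#' (population variance) for determinism; `var_n = "n-1"` switches to the
#' sample variance. `denominator = "realized"` divides by the realized
#' `Var(Z a_hat)` instead of the REML additive variance.
#'
#' @param Z centered dosages of the genotyped animals.
#' @param effects `snp_effects`.
#' @param windows from [define_windows()].
#' @param sigma2_a total additive genetic variance (REML estimate).
#' @param denominator `"sigma2_a"` (default) or `"realized"`.
#' @param var_n `"n"` (default) or `"n-1"`.
#' @return `windows` with a `pct_variance` column, one row per window.
#' @export
window_variance <- function(Z, effects, windows, sigma2_a,
                            denominator = c("sigma2_a", "realized"),
                            var_n = c("n", "n-1")) {
  denominator <- match.arg(denominator)
  var_n <- match.arg(var_n)
  stopifnot(ncol(Z) == nrow(effects), sigma2_a > 0)
  n <- nrow(Z)
  denomf <- if (var_n == "n") n else n - 1L
  pvar <- function(x) sum((x - mean(x))^2) / denomf
  denom <- if (denominator == "sigma2_a") sigma2_a else
    pvar(drop(Z %*% effects$a_hat))
  pct <- vapply(seq_len(nrow(windows)), function(i) {
    j <- windows$first_snp[i]:windows$last_snp[i]
    g <- drop(Z[, j, drop = FALSE] %*% effects$a_hat[j])
    pvar(g) / denom * 100
  }, numeric(1))
  windows$pct_variance <- pct
  windows
}

#' Select windows above the variance threshold
#'
#' Strictly greater than `threshold_pct`, sorted by decreasing percentage.
#' `merge = TRUE` additionally reports merged regions where selected
#' windows overlap on the same chromosome.
#'
#' @param results windows with `pct_variance` from [window_variance()].
#' @param threshold_pct selection threshold in percent (default 1).
#' @param merge also merge overlapping selected windows into regions.
#' @return selected windows (with a `rank` column); when `merge = TRUE`
#'   the merged regions are attached as attribute `"regions"`.
#' @export
select_windows <- function(results, threshold_pct = 1, merge = FALSE) {
  sel <- results[results$pct_variance > threshold_pct, , drop = FALSE]
  sel <- sel[order(-sel$pct_variance), , drop = FALSE]
  if (nrow(sel)) sel$rank <- seq_len(nrow(sel))
  else sel$rank <- integer(0)
  rownames(sel) <- NULL
  if (merge && nrow(sel)) {
    regions <- do.call(rbind, lapply(split(sel, sel$chrom), function(s) {
      s <- s[order(s$start_bp), ]
      grp <- cumsum(c(1, s$start_bp[-1] > cummax(s$end_bp[-nrow(s)])))
      do.call(rbind, lapply(split(s, grp), function(r)
        data.frame(chrom = r$chrom[1], start_bp = min(r$start_bp),
                   end_bp = max(r$end_bp), n_windows = nrow(r),
                   max_pct = max(r$pct_variance))))
    }))
    rownames(regions) <- NULL
    attr(sel, "regions") <- regions
  }
  sel
}

#' Annotate selected windows with overlapping intervals
#'
#' Generic interval intersection of windows against a BED file (or a
#' ready `GRanges`), e.g. gene annotations. Any overlap of at least 1 bp
#' on a matching chromosome label is reported.
#'
#' @param selected windows (rows with `chrom`, `start_bp`, `end_bp`).
#' @param intervals path to a BED file, or a `GRanges`.
#' @return data.frame pairing windows with the names of overlapping
#'   intervals.
#' @export
annotate_windows <- function(selected, intervals) {
  if (is.character(intervals))
    intervals <- rtracklayer::import(intervals, format = "BED")
  if (!nrow(selected))
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), feature = character(0)))
  win <- GenomicRanges::GRanges(
    seqnames = as.character(selected$chrom),
    ranges = IRanges::IRanges(start = selected$start_bp,
                              end = selected$end_bp - 1))
  hits <- GenomicRanges::findOverlaps(win, intervals)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  nm <- S4Vectors::mcols(intervals)$name
  if (is.null(nm)) nm <- paste0("interval_", seq_along(intervals))
  data.frame(chrom = selected$chrom[qh], start_bp = selected$start_bp[qh],
             end_bp = selected$end_bp[qh], feature = nm[sh])
}

#' Iterative weighted single-step GBLUP
#'
#' Iteration 1 is plain single-step GBLUP/GREML (`D = I`); variance
#' components are estimated once there (unless supplied fixed) and held
#' for the re-weighted iterations, which only re-estimate GEBVs.
#' Each iteration back-solves SNP effects from the genotyped animals'
#' GEBVs, converts them to per-SNP variances, and uses those as the
#' weights of the next iteration's `G*`.
#'
#' @inheritParams fit_ssgreml
#' @param n_iterations number of weighting iterations (>= 1; the default 2
#'   runs one re-weighted analysis, since the weighting scheme is known to
#'   overfit beyond 2-3 iterations).
#' @param vc fixed [variance_components()]; `NULL` estimates them by REML
#'   at iteration 1.
#' @return a `wssgblup_run`: list with one element per iteration, each
#'   holding `vc`, `solution`, `effects` and the `weights` used, plus the
#'   shared `freqs`, `Z` and map.
#' @export
run_wssgblup <- function(spec, phenotypes, ped, genotypes, n_iterations = 2L,
                         vc = NULL, blend_alpha = 0.05, tune = TRUE,
                         algorithm = "ai", tol = 1e-8, max_iter = 200L) {
  stopifnot(n_iterations >= 1L)
  if (!has_inbreeding(ped)) ped <- compute_inbreeding(ped)
  A_inv <- build_A_inverse(ped)
  genotyped_ids <- animal_ids(genotypes)
  gcodes <- match(genotyped_ids, ped$id)
  freqs <- allele_frequencies(genotypes)
  Z <- center_dosages(genotypes, freqs)
  A22 <- extract_A22(ped, genotyped_ids)
  designs <- build_design(spec, phenotypes, ped)

  weights <- NULL # iteration 1: D = I
  iterations <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    G <- build_G(Z, freqs, weights)
    if (tune) G <- tune_G(G, A22)
    G <- blend_G(G, A22, blend_alpha)
    H_inv <- build_H_inverse(A_inv, A22, G, gcodes)
    if (it == 1L && is.null(vc)) {
      vc <- reml_estimate(designs, H_inv, algorithm = algorithm, tol = tol,
                          max_iter = max_iter)
    }
    solution <- solve_mme(assemble_mme(designs, H_inv, vc))
    u_g <- solution$u[genotyped_ids]
    effects <- backsolve_snp_effects(Z, weights, u_g,
                                     ZDZt = as.matrix(G) * freqs$two_pq_sum)
    attr(effects, "iteration") <- it - 1L
    effects <- snp_variances(effects, freqs)
    next_weights <- update_weights(effects)
    top5 <- sum(sort(as.numeric(next_weights), decreasing = TRUE)[1:min(5, length(next_weights))])
    if (top5 > 0.99 * sum(as.numeric(next_weights)))
      warning("SNP weight collapse: >99% of weight mass on <= 5 SNPs at iteration ", it)
    iterations[[it]] <- list(iteration = it, vc = vc, solution = solution,
                             effects = effects, weights = weights %||%
                               snp_weights(rep(1, ncol(Z)), 0L))
    weights <- next_weights
  }
  structure(list(iterations = iterations, freqs = freqs, Z = Z,
                 map = genotypes$map, vc = vc,
                 genotyped_ids = genotyped_ids),
            class = "wssgblup_run")
}

#' Window scan of a weighted single-step run
#'
#' Convenience wrapper: defines sliding windows on the post-QC map,
#' computes each window's share of additive variance from the final
#' iteration's SNP effects, and applies the selection threshold.
#'
#' @param run a `wssgblup_run`.
#' @param span_bp window span (default 1 Mb).
#' @param threshold_pct selection threshold (default 1%).
#' @param iteration which iteration's effects to scan (default: last).
#' @return list `windows` (all, with `pct_variance`) and `selected`.
#' @export
scan_windows <- function(run, span_bp = 1e6, threshold_pct = 1,
                         iteration = length(run$iterations)) {
  eff <- run$iterations[[iteration]]$effects
  win <- define_windows(run$map, span_bp)
  win <- window_variance(run$Z, eff, win, run$vc$sigma2_a)
  list(windows = win, selected = select_windows(win, threshold_pct))
}

#' Manhattan-style window table
#'
#' One row per window in genomic order with a cumulative genome position,
#' ready for plotting percentage of additive variance along the genome.
#'
#' @param windows window table with `pct_variance`.
#' @return data.frame with `chrom`, `pos_bp`, `cum_pos_bp`, `pct_variance`.
#' @export
manhattan_table <- function(windows) {
  w <- windows[order(chrom_rank(windows$chrom), windows$start_bp), ]
  sizes <- tapply(w$end_bp, chrom_rank(w$chrom), max)
  offs <- c(0, cumsum(as.numeric(sizes)))[seq_along(sizes)]
  names(offs) <- names(sizes)
  data.frame(chrom = w$chrom, pos_bp = w$start_bp,
             cum_pos_bp = w$start_bp + offs[as.character(chrom_rank(w$chrom))],
             n_snps = w$n_snps, pct_variance = w$pct_variance)
}
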