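# The univariate animal model
#
#   y = mu + X b + Z a + W c + e,
#   a ~ N(0, K sigma2_a),  c ~ N(0, I sigma2_hys),  e ~ N(0, I sigma2_e)
#
# with K the pedigree (A), genomic (G) or single-step (H) relationship
# matrix, c the herd-year-season contemporary-group effect, and the trait
# profiles fixing which covariates/factors enter X. Variance components by
# REML (observation-scale AI with exact derivatives, or MME-based EM), and
# BLUE/BLUP solutions from Henderson's mixed-model equations.

#' Trait model specification
#'
#' Encodes the fixed-effect structure per fertility trait:
#' * `AFC` (age at first calving, months): intercept only;
#' * `IC12`, `ACI` (calving intervals, months): inbreeding covariate `F`
#'   plus the 3-level age-at-first-calving class factor;
#' * `RE` (reproductive efficiency, %): as `IC12` plus the
#'   age-at-last-calving covariate.
#'
#' Class thresholds for the AFC factor are fixed at `< 30`, `[30, 36)` and
#' `>= 36` months. All traits carry the random additive and random HYS
#' terms.
#'
#' @param trait one of `"AFC"`, `"IC12"`, `"ACI"`, `"RE"`, `"custom"`.
#' @param covariates,factors for `trait = "custom"`, the names of the
#'   phenotype-table columns used as fixed covariates / class factors.
#' @return a `trait_model_spec` list.
#' @export
trait_model_spec <- function(trait = c("AFC", "IC12", "ACI", "RE", "custom"),
                             covariates = NULL, factors = NULL) {
  trait <- match.arg(trait)
  layout <- switch(trait,
    AFC = list(covariates = character(0), factors = character(0)),
    IC12 = ,
    ACI = list(covariates = "F", factors = "afc_class"),
    RE = list(covariates = c("F", "age_last_calving"), factors = "afc_class"),
    custom = list(covariates = covariates %||% character(0),
                  factors = factors %||% character(0)))
  structure(c(list(trait = trait), layout), class = "trait_model_spec")
}

#' Age-at-first-calving class
#'
#' @param afc_months age at first calving in months.
#' @return integer class: 1 (`< 30`), 2 (`[30, 36)`), 3 (`>= 36`).
#' @export
afc_class <- function(afc_months) {
  findInterval(afc_months, c(30, 36)) + 1L
}

#' Read a phenotype CSV
#'
#' Columns `animal,value,hys[,F,age_last_calving,afc_class]`. Records are
#' canonically sorted by animal id (then HYS) on ingest so downstream
#' results do not depend on file row order.
#'
#' @param path CSV file.
#' @return data.frame of phenotype records.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(c("animal", "value", "hys") %in% names(df)))
  df$animal <- as.character(df$animal)
  df[order(df$animal, df$hys), , drop = FALSE]
}

#' Build the design matrices of the animal model
#'
#' `X` is `[1 | covariates | factor dummies]` with the first level of each
#' factor dropped; `Z` maps each record to its animal's position in the
#' pedigree (one column per pedigree animal, so non-phenotyped animals get
#' breeding values); `W` maps records to herd-year-season levels.
#'
#' @param spec [trait_model_spec()].
#' @param phenotypes data.frame with columns `animal`, `value`, `hys` and
#'   whatever the spec's covariates/factors name.
#' @param ped sorted `pedigree_table` containing every phenotyped animal.
#' @return list with `X`, `Z`, `W` (sparse), `y`, the HYS level table and
#'   bookkeeping dimensions.
#' @export
build_design <- function(spec, phenotypes, ped) {
  stopifnot(inherits(spec, "trait_model_spec"))
  stopifnot_pedigree(ped)
  ph <- phenotypes
  stopifnot(all(c("animal", "value", "hys") %in% names(ph)))
  if (anyNA(ph$value)) stop("missing trait values in modeled records")
  codes <- match(as.character(ph$animal), ped$id)
  if (anyNA(codes))
    stop("phenotyped animal(s) absent from pedigree: ",
         paste(head(ph$animal[is.na(codes)], 5), collapse = ", "))
  n <- nrow(ph)

  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in spec$covariates) {
    if (is.null(ph[[cv]])) stop("covariate column missing: ", cv)
    X <- cbind(X, matrix(as.numeric(ph[[cv]]), ncol = 1,
                         dimnames = list(NULL, cv)))
  }
  for (fc in spec$factors) {
    if (is.null(ph[[fc]])) stop("factor column missing: ", fc)
    f <- factor(ph[[fc]])
    if (nlevels(f) > 1L) {
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(fc, levels(f)[-1])
      X <- cbind(X, mm)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient fixed-effect matrix; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }

  hys <- factor(ph$hys)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = codes, x = 1,
                            dims = c(n, nrow(ped)))
  W <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(hys), x = 1,
                            dims = c(n, nlevels(hys)))
  list(X = X, Z = Z, W = W, y = as.numeric(ph$value),
       animal_codes = codes, hys_levels = levels(hys),
       n_records = n, n_ped = nrow(ped), n_hys = nlevels(hys),
       rank_X = qrX$rank, ped_ids = ped$id, spec = spec)
}

#' Variance components container
#'
#' @param sigma2_a,sigma2_hys,sigma2_e additive, herd-year-season and
#'   residual variances (trait units squared).
#' @param se optional standard errors (named).
#' @param n_iter,converged,loglik REML bookkeeping.
#' @return `variance_components` list with derived heritability
#'   `h2 = sigma2_a / (sigma2_a + sigma2_hys + sigma2_e)`.
#' @export
variance_components <- function(sigma2_a, sigma2_hys, sigma2_e, se = NULL,
                                n_iter = NA_integer_, converged = NA,
                                loglik = NA_real_) {
  stopifnot(sigma2_a > 0, sigma2_hys >= 0, sigma2_e > 0)
  structure(list(sigma2_a = sigma2_a, sigma2_hys = sigma2_hys,
                 sigma2_e = sigma2_e,
                 h2 = sigma2_a / (sigma2_a + sigma2_hys + sigma2_e),
                 se = se, n_iter = n_iter, converged = converged,
                 loglik = loglik),
            class = "variance_components")
}

#' @method print variance_components
#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "variance components: sigma2_a = %.4g, sigma2_hys = %.4g, sigma2_e = %.4g\n",
    x$sigma2_a, x$sigma2_hys, x$sigma2_e))
  cat(sprintf("heritability h2 = %.4f%s\n", x$h2,
              if (!is.na(x$n_iter)) sprintf("  (REML, %d iterations)", x$n_iter) else ""))
  invisible(x)
}

#' Serialize variance components to JSON
#' @param vc `variance_components`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vc_json <- function(vc, path) {
  jsonlite::write_json(
    list(sigma2_a = vc$sigma2_a, sigma2_hys = vc$sigma2_hys,
         sigma2_e = vc$sigma2_e, h2 = vc$h2,
         se = as.list(vc$se %||% list()), n_iter = vc$n_iter),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assemble Henderson's mixed-model equations
#'
#' Coefficient matrix
#' `C = [[X'X, X'Z, X'W], [Z'X, Z'Z + K^{-1} la, Z'W], [W'X, W'Z, W'W + I lc]]`
#' with `la = sigma2_e / sigma2_a`, `lc = sigma2_e / sigma2_hys`, and right
#' hand side `[X'y, Z'y, W'y]`.
#'
#' @param designs from [build_design()].
#' @param K_inv sparse relationship inverse for the additive term (A, G or
#'   H inverse), dimension `n_ped`.
#' @param vc [variance_components()] (all components positive).
#' @return list `C` (sparse symmetric), `rhs`, block dimensions.
#' @export
assemble_mme <- function(designs, K_inv, vc) {
  stopifnot(vc$sigma2_a > 0, vc$sigma2_hys > 0, vc$sigma2_e > 0)
  X <- as(designs$X, "CsparseMatrix"); Z <- designs$Z; W <- designs$W
  y <- designs$y
  la <- vc$sigma2_e / vc$sigma2_a
  lc <- vc$sigma2_e / vc$sigma2_hys
  Kl <- as(K_inv, "CsparseMatrix") * la
  C <- rbind(
    cbind(Matrix::crossprod(X), Matrix::crossprod(X, Z), Matrix::crossprod(X, W)),
    cbind(Matrix::crossprod(Z, X), Matrix::crossprod(Z) + Kl, Matrix::crossprod(Z, W)),
    cbind(Matrix::crossprod(W, X), Matrix::crossprod(W, Z),
          Matrix::crossprod(W) + Matrix::Diagonal(ncol(W)) * lc))
  rhs <- c(as.numeric(Matrix::crossprod(X, y)),
           as.numeric(Matrix::crossprod(Z, y)),
           as.numeric(Matrix::crossprod(W, y)))
  list(C = Matrix::forceSymmetric(C, uplo = "U"), rhs = rhs,
       p = ncol(X), n_ped = ncol(Z), n_hys = ncol(W),
       fixed_names = colnames(designs$X), ped_ids = designs$ped_ids,
       hys_levels = designs$hys_levels)
}

#' Solve the mixed-model equations
#'
#' @param mme assembled system from [assemble_mme()].
#' @param method `"direct"` (sparse Cholesky) or `"pcg"`
#'   (Jacobi-preconditioned conjugate gradients).
#' @param tol relative residual tolerance for PCG.
#' @param max_iter PCG iteration cap.
#' @return an `mme_solution`: fixed effects `b`, breeding values `u` (one
#'   per pedigree animal, GEBVs under an H-inverse), HYS solutions `c`,
#'   and the achieved relative residual `convergence`.
#' @export
solve_mme <- function(mme, method = c("direct", "pcg"), tol = 1e-10,
                      max_iter = 5000L) {
  method <- match.arg(method)
  C <- mme$C; rhs <- mme$rhs
  if (method == "direct") {
    x <- as.numeric(Matrix::solve(C, rhs))
  } else {
    x <- pcg_solve(C, rhs, tol = tol, max_iter = max_iter)
  }
  res <- max(abs(as.numeric(C %*% x) - rhs)) / max(abs(rhs))
  idx_b <- seq_len(mme$p)
  idx_u <- mme$p + seq_len(mme$n_ped)
  idx_c <- mme$p + mme$n_ped + seq_len(mme$n_hys)
  structure(list(
    b = stats::setNames(x[idx_b], mme$fixed_names),
    u = stats::setNames(x[idx_u], mme$ped_ids),
    c = stats::setNames(x[idx_c], mme$hys_levels),
    convergence = res, method = method), class = "mme_solution")
}

pcg_solve <- function(C, rhs, tol = 1e-10, max_iter = 5000L) {
  dinv <- 1 / Matrix::diag(C)
  x <- numeric(length(rhs))
  r <- rhs
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(rhs^2))
  for (it in seq_len(max_iter)) {
    Cp <- as.numeric(C %*% p)
    alpha <- rz / sum(p * Cp)
    x <- x + alpha * p
    r <- r - alpha * Cp
    if (sqrt(sum(r^2)) / bnorm < tol) return(x)
    z <- dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf(
    "PCG did not converge in %d iterations (relative residual %.3g)",
    max_iter, sqrt(sum(r^2)) / bnorm))
}

#' REML estimation of the three variance components
#'
#' `algorithm = "ai"` (default) maximizes the restricted likelihood on the
#' observation scale, `V = sigma2_a M + sigma2_hys W W' + sigma2_e I` with
#' `M = Z K Z'`, using average-information updates with exact first
#' derivatives; a proposed step that would drive a component non-positive
#' is halved until admissible. `algorithm = "em"` runs the classical
#' expectation-maximization recursion on Henderson's equations
#' (`sigma2_a' = (u' K^{-1} u + sigma2_e tr(K^{-1} C^{uu})) / n_ped`, the
#' analogous HYS update, and the residual from `y'y - sol'rhs`); it is
#' slow but derivative-free and serves as an independent cross-check.
#'
#' @param designs from [build_design()].
#' @param K_inv sparse relationship inverse (dimension `n_ped`).
#' @param init starting [variance_components()]; default splits the
#'   phenotypic variance equally.
#' @param algorithm `"ai"` or `"em"`.
#' @param max_iter iteration cap (an error carrying the trajectory is
#'   raised on non-convergence).
#' @param tol convergence threshold on the maximum relative component
#'   change between iterations.
#' @param K_obs optional precomputed `M = Z K Z'` (observation-scale
#'   relationship block); computed from `K_inv` by sparse Cholesky solves
#'   when absent.
#' @return converged [variance_components()] with standard errors from the
#'   inverse average-information matrix (AI path).
#' @export
reml_estimate <- function(designs, K_inv, init = NULL,
                          algorithm = c("ai", "em"), max_iter = 200L,
                          tol = 1e-8, K_obs = NULL) {
  algorithm <- match.arg(algorithm)
  vp <- stats::var(designs$y)
  if (is.null(init)) init <- variance_components(vp / 3, vp / 3, vp / 3)
  theta0 <- c(init$sigma2_a, init$sigma2_hys, init$sigma2_e)
  if (algorithm == "ai") {
    M <- K_obs %||% observation_K(designs, K_inv)
    fit <- reml_ai(designs, M, theta0, max_iter = max_iter, tol = tol)
  } else {
    fit <- reml_em(designs, K_inv, theta0, max_iter = max_iter, tol = tol)
  }
  if (!fit$converged) {
    cond <- structure(class = c("reml_nonconvergence", "error", "condition"),
                      list(message = sprintf(
                        "REML (%s) did not converge in %d iterations (last max relative change %.3g)",
                        algorithm, fit$n_iter, fit$last_change),
                        call = NULL, trajectory = fit$trajectory,
                        last = fit$theta))
    stop(cond)
  }
  variance_components(fit$theta[1], fit$theta[2], fit$theta[3],
                      se = fit$se, n_iter = fit$n_iter, converged = TRUE,
                      loglik = fit$loglik)
}

# M = Z K Z' for the phenotyped animals, obtained from K^{-1} by sparse
# Cholesky solves against unit columns (K itself is never formed).
observation_K <- function(designs, K_inv) {
  codes <- designs$animal_codes
  need <- sort(unique(codes))
  n_ped <- designs$n_ped
  E <- Matrix::sparseMatrix(i = need, j = seq_along(need), x = 1,
                            dims = c(n_ped, length(need)))
  Kcols <- as.matrix(Matrix::solve(Matrix::forceSymmetric(as(K_inv, "CsparseMatrix")), E))
  Ksub <- Kcols[need, , drop = FALSE]
  idx <- match(codes, need)
  M <- Ksub[idx, idx, drop = FALSE]
  (M + t(M)) / 2
}

reml_ai <- function(designs, M, theta, max_iter = 200L, tol = 1e-8) {
  y <- designs$y
  X <- designs$X
  n <- length(y)
  Q <- as.matrix(Matrix::tcrossprod(designs$W))
  vp <- stats::var(y)
  floor_ <- 1e-8 * vp
  trajectory <- list()
  converged <- FALSE
  ll <- NA_real_; ll_prev <- NA_real_; AI <- NULL; rel <- Inf
  for (it in seq_len(max_iter)) {
    V <- theta[1] * M + theta[2] * Q + diag(theta[3], n)
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) { # bend: inflate the residual slightly
      theta[3] <- theta[3] * 1.5 + floor_
      next
    }
    Vi <- chol2inv(cV)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    cXX <- chol(XtViX)
    P <- Vi - ViX %*% chol2inv(cXX) %*% t(ViX)
    Py <- drop(P %*% y)
    MPy <- drop(M %*% Py); QPy <- drop(Q %*% Py)
    sc <- -0.5 * c(sum(P * M) - sum(Py * MPy),
                   sum(P * Q) - sum(Py * QPy),
                   sum(diag(P)) - sum(Py * Py))
    PMPy <- drop(P %*% MPy); PQPy <- drop(P %*% QPy); PPy <- drop(P %*% Py)
    AI <- 0.5 * rbind(
      c(sum(MPy * PMPy), sum(MPy * PQPy), sum(MPy * PPy)),
      c(sum(MPy * PQPy), sum(QPy * PQPy), sum(QPy * PPy)),
      c(sum(MPy * PPy), sum(QPy * PPy), sum(Py * PPy)))
    ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cXX))) +
                    sum(Py * y))
    # a component on the positivity floor whose score still points down
    # is pinned there, and the AI system is solved over the free
    # components only -- otherwise the ill-conditioned boundary row
    # poisons the whole direction and the step collapses
    free <- !(theta <= floor_ * 1.001 & sc < 0)
    delta <- numeric(3)
    if (any(free))
      delta[free] <- tryCatch(
        solve(AI[free, free, drop = FALSE], sc[free]),
        error = function(e) sc[free] / pmax(diag(AI)[free], 1e-12))
    step <- 1
    repeat {
      thn <- theta + step * delta
      if (all(thn[free] > floor_)) break
      step <- step / 2
      if (step < 1e-4) { thn <- pmax(theta + step * delta, floor_); break }
    }
    thn <- pmax(thn, floor_)
    rel <- max(abs(thn - theta) / (abs(theta) + 1e-6 * vp))
    trajectory[[it]] <- c(theta = thn, loglik = ll)
    theta <- thn
    ll_stalled <- it > 3 && is.finite(ll_prev) &&
      abs(ll - ll_prev) < 1e-9 * (abs(ll) + 1)
    ll_prev <- ll
    if (rel < tol || ll_stalled) { converged <- TRUE; break }
  }
  se_th <- tryCatch(sqrt(diag(solve(AI))), error = function(e) rep(NA_real_, 3))
  se <- c(sigma2_a = se_th[1], sigma2_hys = se_th[2], sigma2_e = se_th[3],
          h2 = h2_se(theta, AI))
  list(theta = theta, se = se, n_iter = it, converged = converged,
       loglik = ll, trajectory = trajectory, last_change = rel)
}

# delta-method SE of h2 = t1/(t1+t2+t3) from the inverse AI matrix
h2_se <- function(theta, AI) {
  Vth <- tryCatch(solve(AI), error = function(e) return(NA_real_))
  if (!is.matrix(Vth)) return(NA_real_)
  s <- sum(theta)
  grad <- c(s - theta[1], -theta[1], -theta[1]) / s^2
  sqrt(max(drop(t(grad) %*% Vth %*% grad), 0))
}

reml_em <- function(designs, K_inv, theta, max_iter = 2000L, tol = 1e-8) {
  y <- designs$y
  n <- designs$n_records; q <- designs$n_ped; r <- designs$n_hys
  Kd <- as.matrix(K_inv)
  vp <- stats::var(y)
  trajectory <- list()
  converged <- FALSE
  rel <- Inf
  for (it in seq_len(max_iter)) {
    vc <- variance_components(theta[1], max(theta[2], 1e-10 * vp), theta[3])
    mme <- assemble_mme(designs, K_inv, vc)
    Cd <- as.matrix(mme$C)
    Ci <- solve(Cd)
    sol <- drop(Ci %*% mme$rhs)
    iu <- mme$p + seq_len(q)
    ic <- mme$p + q + seq_len(r)
    u <- sol[iu]; cc <- sol[ic]
    Cuu <- Ci[iu, iu]; Ccc <- Ci[ic, ic]
    sa <- (drop(t(u) %*% Kd %*% u) + theta[3] * sum(Kd * Cuu)) / q
    sh <- (sum(cc^2) + theta[3] * sum(diag(Ccc))) / r
    se2 <- (sum(y^2) - sum(sol * mme$rhs)) / (n - designs$rank_X)
    thn <- c(sa, sh, se2)
    rel <- max(abs(thn - theta) / (abs(theta) + 1e-6 * vp))
    trajectory[[it]] <- c(theta = thn)
    theta <- thn
    if (rel < tol) { converged <- TRUE; break }
  }
  list(theta = theta, se = NULL, n_iter = it, converged = converged,
       loglik = NA_real_, trajectory = trajectory, last_change = rel)
}

#' Single-step GREML fit
#'
#' Orchestrates the pieces of one evaluation: inbreeding and sparse
#' A-inverse from the pedigree, VanRaden G (optionally SNP-weighted),
#' blending, A22, the H-inverse, REML variance components, and finally
#' the mixed-model solve for GEBVs of every pedigree animal. With
#' `genotypes = NULL` this reduces exactly to pedigree BLUP/REML.
#'
#' @param spec [trait_model_spec()].
#' @param phenotypes phenotype records (see [build_design()]).
#' @param ped sorted `pedigree_table`.
#' @param genotypes post-QC [genotype_matrix()] of the genotyped animals,
#'   or `NULL` for the pedigree-only model.
#' @param vc_init starting values for REML, or the fixed components used
#'   as-is when `reml = FALSE`.
#' @param weights optional [snp_weights()] for a weighted `G*`.
#' @param blend_alpha pedigree admixture in G (see [blend_G()]).
#' @param tune rescale G to the pedigree base before blending (see
#'   [tune_G()]); on by default, mirroring routine evaluation software.
#' @param reml estimate components (`TRUE`) or hold `vc_init` fixed.
#' @param solve also solve the mixed-model equations for effects/GEBVs.
#' @param algorithm,tol,max_iter passed to [reml_estimate()].
#' @return an `ssgreml_fit` list: `vc`, `solution` (or `NULL`), and the
#'   reusable intermediates (`A_inv`, `A22`, `Z`, `freqs`, `G`, `H_inv`,
#'   `designs`, `genotyped_ids`).
#' @export
fit_ssgreml <- function(spec, phenotypes, ped, genotypes = NULL,
                        vc_init = NULL, weights = NULL, blend_alpha = 0.05,
                        tune = TRUE, reml = TRUE, solve = TRUE,
                        algorithm = "ai", tol = 1e-8, max_iter = 200L) {
  stopifnot_pedigree(ped)
  if (!has_inbreeding(ped)) ped <- compute_inbreeding(ped)
  A_inv <- build_A_inverse(ped)
  Z <- freqs <- G <- A22 <- NULL
  genotyped_ids <- character(0)
  if (!is.null(genotypes)) {
    genotyped_ids <- animal_ids(genotypes)
    freqs <- allele_frequencies(genotypes)
    Z <- center_dosages(genotypes, freqs)
    G0 <- build_G(Z, freqs, weights)
    A22 <- extract_A22(ped, genotyped_ids)
    if (tune) G0 <- tune_G(G0, A22)
    G <- blend_G(G0, A22, blend_alpha)
    K_inv <- build_H_inverse(A_inv, A22, G, match(genotyped_ids, ped$id))
  } else {
    K_inv <- A_inv
  }
  designs <- build_design(spec, phenotypes, ped)
  if (reml) {
    vc <- reml_estimate(designs, K_inv, init = vc_init,
                        algorithm = algorithm, tol = tol,
                        max_iter = max_iter)
  } else {
    stopifnot(inherits(vc_init, "variance_components"))
    vc <- vc_init
  }
  solution <- if (solve) solve_mme(assemble_mme(designs, K_inv, vc)) else NULL
  structure(list(vc = vc, solution = solution, spec = spec,
                 A_inv = A_inv, A22 = A22, Z = Z, freqs = freqs, G = G,
                 H_inv = K_inv, designs = designs,
                 genotyped_ids = genotyped_ids, ped = ped),
            class = "ssgreml_fit")
}

#' @method print ssgreml_fit
#' @export
print.ssgreml_fit <- function(x, ...) {
  cat(sprintf("<single-step GREML fit: trait %s, %d records, %d pedigree animals, %d genotyped>\n",
              x$spec$trait, x$designs$n_records, x$designs$n_ped,
              length(x$genotyped_ids)))
  print(x$vc)
  invisible(x)
}
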