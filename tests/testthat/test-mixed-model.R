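# Design matrices, Henderson's equations and their solvers, REML by the
# two independent routes, and the orchestration in fit_ssgreml.

make_phen <- function(ped, seed = 1, n = nrow(ped), vc = list(a = 4, h = 2, e = 6),
                      mu = 10) {
  set.seed(seed)
  ped <- compute_inbreeding(ped)
  ids <- sample(ped$id, n, replace = FALSE)
  A <- unclass(build_A_tabular(ped))
  u <- drop(t(chol(A + diag(1e-8, nrow(A)))) %*% rnorm(nrow(A))) * sqrt(vc$a)
  hys <- sample(1:4, n, replace = TRUE)
  he <- rnorm(4, 0, sqrt(vc$h))
  data.frame(animal = ids, value = mu + u[match(ids, ped$id)] + he[hys] +
               rnorm(n, 0, sqrt(vc$e)),
             hys = hys, F = ped$F[match(ids, ped$id)],
             age_last_calving = rnorm(n, 9, 2),
             afc_class = sample(1:3, n, replace = TRUE))
}

test_that("trait profiles impose the fixed-effect exclusion rules", {
  expect_equal(trait_model_spec("AFC")$covariates, character(0))
  expect_equal(trait_model_spec("AFC")$factors, character(0))
  expect_setequal(trait_model_spec("IC12")$covariates, "F")
  expect_setequal(trait_model_spec("RE")$covariates, c("F", "age_last_calving"))
  expect_equal(trait_model_spec("ACI")$factors, "afc_class")
  expect_equal(afc_class(c(17, 29.9, 30, 35.9, 36, 49)),
               c(1L, 1L, 2L, 2L, 3L, 3L))

  ped <- rand_pedigree(20, seed = 1)
  ph <- make_phen(ped, n = 5)
  d <- build_design(trait_model_spec("AFC"), ph, ped)
  expect_equal(colnames(d$X), "(Intercept)") # AFC: mean only
  dre <- build_design(trait_model_spec("RE"), ph, ped)
  expect_setequal(colnames(dre$X),
                  c("(Intercept)", "F", "age_last_calving",
                    paste0("afc_class", sort(unique(ph$afc_class))[-1])))
})

test_that("design matrices match brute-force accumulation", {
  ped <- rand_pedigree(30, seed = 2)
  ph <- make_phen(ped, seed = 2, n = 25)
  d <- build_design(trait_model_spec("RE"), ph, ped)

  # W'W is the HYS level count diagonal
  expect_equal(as.matrix(Matrix::crossprod(d$W)),
               diag(as.numeric(table(ph$hys))), ignore_attr = TRUE)

  # X'X from a record-by-record loop
  XtX <- matrix(0, ncol(d$X), ncol(d$X))
  for (i in seq_len(nrow(ph))) XtX <- XtX + tcrossprod(d$X[i, ])
  expect_equal(unname(crossprod(d$X)), XtX, tolerance = 1e-12)

  # each record hits exactly its animal's pedigree position
  expect_equal(Matrix::rowSums(d$Z), rep(1, nrow(ph)), ignore_attr = TRUE)
  expect_equal(which(as.matrix(d$Z[1, ]) != 0), match(ph$animal[1], ped$id))

  # an aliased covariate is reported by name
  ph2 <- ph; ph2$dupF <- ph2$F
  spec2 <- trait_model_spec("custom", covariates = c("F", "dupF"))
  expect_error(build_design(spec2, ph2, ped), "dupF")

  # unknown animals are reported
  ph3 <- ph; ph3$animal[1] <- "stranger"
  expect_error(build_design(trait_model_spec("RE"), ph3, ped), "stranger")
})

test_that("the assembled equations have Henderson's structure", {
  ped <- rand_pedigree(15, seed = 3)
  ph <- make_phen(ped, seed = 3, n = 12)
  d <- build_design(trait_model_spec("ACI"), ph, ped)
  Kinv <- build_A_inverse(ped)
  vc <- variance_components(2, 1, 4)
  mme <- assemble_mme(d, Kinv, vc)
  expect_equal(dim(mme$C), rep(mme$p + mme$n_ped + mme$n_hys, 2))
  expect_lt(max(abs(as.matrix(mme$C - Matrix::t(mme$C)))), 1e-12)

  iu <- mme$p + seq_len(mme$n_ped)
  blk <- as.matrix(mme$C[iu, iu])
  lam <- vc$sigma2_e / vc$sigma2_a
  expect_equal(blk, as.matrix(Matrix::crossprod(d$Z) + lam * Kinv),
               ignore_attr = TRUE, tolerance = 1e-12)

  # sigma2_a -> infinity limit: additive block approaches Z'Z
  mme0 <- assemble_mme(d, Kinv, variance_components(1e12, 1, 4))
  expect_equal(as.matrix(mme0$C[iu, iu]), as.matrix(Matrix::crossprod(d$Z)),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("solve_mme agrees with dense GLS, PCG with direct, and respects parent averaging", {
  ped <- rand_pedigree(10, seed = 4)
  ph <- make_phen(ped, seed = 4, n = 8)
  d <- build_design(trait_model_spec("AFC"), ph, ped)
  vc <- variance_components(3, 1.5, 5)
  Kinv <- build_A_inverse(ped)
  sol <- solve_mme(assemble_mme(d, Kinv, vc))
  expect_lt(sol$convergence, 1e-8)

  A <- unclass(build_A_tabular(ped))
  gls <- gls_oracle(d$y, d$X, d$Z, d$W, A, vc)
  expect_equal(unname(sol$b), unname(gls$b), tolerance = 1e-8)
  expect_equal(unname(sol$u), unname(gls$u), tolerance = 1e-8)
  expect_equal(unname(sol$c), unname(gls$c), tolerance = 1e-8)

  # identity system
  id_mme <- list(C = Matrix::Diagonal(4), rhs = c(1, 2, 3, 4), p = 1L,
                 n_ped = 2L, n_hys = 1L, fixed_names = "mu",
                 ped_ids = c("a", "b"), hys_levels = "h1")
  expect_equal(unname(unlist(solve_mme(id_mme)[c("b", "u", "c")])),
               c(1, 2, 3, 4))

  # direct vs Jacobi-PCG on a bigger system
  ped2 <- rand_pedigree(150, seed = 5)
  ph2 <- make_phen(ped2, seed = 5, n = 120)
  d2 <- build_design(trait_model_spec("ACI"), ph2, ped2)
  mme2 <- assemble_mme(d2, build_A_inverse(ped2), vc)
  s_dir <- solve_mme(mme2, method = "direct")
  s_pcg <- solve_mme(mme2, method = "pcg", tol = 1e-12)
  expect_equal(s_pcg$u, s_dir$u, tolerance = 1e-6)
  expect_error(solve_mme(mme2, method = "pcg", max_iter = 2L), "PCG")

  # childless, recordless animal's GEBV is its parents' average
  ped3 <- as_pedigree_table(data.frame(
    animal = c("s", "d", "o1", "tip"), sire = c("", "", "s", "s"),
    dam = c("", "", "d", "d")))
  ph3 <- data.frame(animal = c("s", "d", "o1"), value = c(12, 9, 11),
                    hys = c(1, 1, 2))
  d3 <- build_design(trait_model_spec("AFC"), ph3, ped3)
  s3 <- solve_mme(assemble_mme(d3, build_A_inverse(ped3), vc))
  expect_equal(s3$u[["tip"]], mean(s3$u[c("s", "d")]), tolerance = 1e-10)
})

test_that("AI-REML and EM-REML find the same optimum from the same start", {
  ped <- rand_pedigree(60, seed = 6)
  ph <- make_phen(ped, seed = 6, n = 50, vc = list(a = 4, h = 2, e = 6))
  d <- build_design(trait_model_spec("ACI"), ph, ped)
  Kinv <- build_A_inverse(ped)
  fit_ai <- reml_estimate(d, Kinv, algorithm = "ai", tol = 1e-10)
  fit_em <- reml_estimate(d, Kinv, algorithm = "em", tol = 1e-9,
                          max_iter = 5000L)
  expect_equal(fit_em$sigma2_a, fit_ai$sigma2_a, tolerance = 1e-4)
  expect_equal(fit_em$sigma2_hys, fit_ai$sigma2_hys, tolerance = 1e-4)
  expect_equal(fit_em$sigma2_e, fit_ai$sigma2_e, tolerance = 1e-4)
  expect_true(fit_ai$converged)
  expect_true(all(c(fit_ai$sigma2_a, fit_ai$sigma2_hys, fit_ai$sigma2_e) > 0))
  expect_true(fit_ai$h2 > 0 && fit_ai$h2 < 1)
  expect_true(all(is.finite(fit_ai$se)))

  # non-convergence raises a condition carrying the trajectory
  err <- tryCatch(reml_estimate(d, Kinv, algorithm = "ai", max_iter = 2L,
                                tol = 1e-14),
                  reml_nonconvergence = function(e) e)
  expect_s3_class(err, "reml_nonconvergence")
  expect_true(length(err$trajectory) >= 1)
})

test_that("REML is invariant to record order and shifts only move the intercept", {
  ped <- rand_pedigree(50, seed = 7)
  ph <- make_phen(ped, seed = 7, n = 40)
  d <- build_design(trait_model_spec("ACI"), ph, ped)
  Kinv <- build_A_inverse(ped)
  vc1 <- reml_estimate(d, Kinv, tol = 1e-9)

  perm <- sample(nrow(ph))
  d2 <- build_design(trait_model_spec("ACI"), ph[perm, ], ped)
  vc2 <- reml_estimate(d2, Kinv, tol = 1e-9)
  expect_equal(vc2$h2, vc1$h2, tolerance = 1e-6)

  ph3 <- ph; ph3$value <- ph3$value + 100
  d3 <- build_design(trait_model_spec("ACI"), ph3, ped)
  vc3 <- reml_estimate(d3, Kinv, tol = 1e-9)
  expect_equal(vc3$sigma2_a, vc1$sigma2_a, tolerance = 1e-6)
  s1 <- solve_mme(assemble_mme(d, Kinv, vc1))
  s3 <- solve_mme(assemble_mme(d3, Kinv, vc1))
  expect_equal(s3$b[["(Intercept)"]] - s1$b[["(Intercept)"]], 100,
               tolerance = 1e-8)
  expect_equal(s3$u, s1$u, tolerance = 1e-8)
})

test_that("fit_ssgreml without genotypes is exactly pedigree REML/BLUP", {
  ped <- rand_pedigree(40, seed = 8)
  ph <- make_phen(ped, seed = 8, n = 30)
  fit <- fit_ssgreml(trait_model_spec("ACI"), ph, ped, NULL, tol = 1e-9)
  d <- build_design(trait_model_spec("ACI"), ph, compute_inbreeding(ped))
  Kinv <- build_A_inverse(ped)
  vc <- reml_estimate(d, Kinv, tol = 1e-9)
  expect_equal(fit$vc$h2, vc$h2, tolerance = 1e-10)
  expect_equal(fit$solution$u, solve_mme(assemble_mme(d, Kinv, vc))$u,
               tolerance = 1e-10)

  # fixed components are honored when reml = FALSE
  vfix <- variance_components(2, 1, 3)
  ffix <- fit_ssgreml(trait_model_spec("ACI"), ph, ped, NULL,
                      vc_init = vfix, reml = FALSE)
  expect_identical(ffix$vc$h2, vfix$h2)
})
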