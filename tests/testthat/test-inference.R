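test_that("degradation rates are the steady-state U/S ratio", {
  U <- matrix(c(2, 2, 1, 1), 2, 2)   # gene means: U = (2, 1)
  S <- matrix(c(4, 4, 1, 1), 2, 2)   # gene means: S = (4, 1)
  ds <- splice_dataset(U, S, c("A", "A"), gene_names = c("g1", "g2"))
  expect_equal(unname(infer_degradation_rates(ds)), c(0.5, 1))
  expect_equal(unname(infer_degradation_rates(ds, beta = 2)), c(1, 2))
  ds0 <- splice_dataset(U, S * 0, c("A", "A"), gene_names = c("g1", "g2"))
  expect_error(infer_degradation_rates(ds0), "g1, g2")
})

test_that("noiseless linear data is recovered to solver tolerance", {
  A_star <- matrix(c(0, 0.5, -0.3,
                     0.2, 0, 0.4,
                     -0.1, 0.6, 0), 3, 3, byrow = TRUE)
  ds <- make_linear_dataset(60, A_star, A0 = c(2, 2, 3))
  fit <- splice_fit(ds, method = "linear", nboot = 1, frac = 1)
  expect_lt(max(abs(coef(fit, "A") - A_star)), 1e-8)
  expect_equal(unname(fit$models$A$A0), c(2, 2, 3), tolerance = 1e-8)
  expect_equal(unname(diag(coef(fit, "A"))), rep(0, 3))
})

test_that("intercept-only data yields zero interactions and A0 = c", {
  set.seed(1)
  S <- matrix(runif(80 * 2, 1, 5), 80, 2)
  U <- matrix(7, 80, 2)
  ds <- splice_dataset(U, S, rep("A", 80), gene_names = c("g1", "g2"))
  fit <- splice_fit(ds, method = "linear", nboot = 1, frac = 1)
  expect_lt(max(abs(coef(fit, "A"))), 1e-10)
  expect_equal(unname(fit$models$A$A0), c(7, 7))
})

test_that("every gene's coefficients match the normal-equation oracle", {
  A_star <- matrix(c(0, -0.4, 0.3, 0), 2, 2, byrow = TRUE)
  ds <- make_linear_dataset(50, A_star, noise_sd = 0.5, seed = 7)
  U <- as.matrix(ds$U); S <- as.matrix(ds$S)
  fit <- splice_fit(ds, method = "linear", nboot = 1, frac = 1)
  for (i in 1:2) {
    cf <- oracle_gene_fit(S, U, i)
    expect_equal(fit$models$A$A0[[i]], unname(cf[1]), tolerance = 1e-8)
    expect_equal(coef(fit, "A")[i, -i], cf[-1], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # ridge path against the penalized oracle (intercept unpenalized)
  lam <- 2.5
  fitr <- splice_fit(ds, method = "ridge", lambda = lam, nboot = 1, frac = 1)
  for (i in 1:2) {
    cf <- oracle_gene_fit(S, U, i, lam = lam)
    expect_equal(fitr$models$A$A0[[i]], unname(cf[1]), tolerance = 1e-8)
    expect_equal(coef(fitr, "A")[i, -i], cf[-1], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap mean with nboot = 1, frac = 1 equals the full fit", {
  A_star <- matrix(c(0, 0.2, -0.5, 0), 2, 2, byrow = TRUE)
  ds <- make_linear_dataset(40, A_star, noise_sd = 1, seed = 3)
  f1 <- splice_fit(ds, method = "linear", nboot = 1, frac = 1, seed = 11)
  f2 <- splice_fit(ds, method = "linear", nboot = 1, frac = 1, seed = 99)
  expect_identical(coef(f1, "A"), coef(f2, "A"))  # subsample = all cells
  U <- as.matrix(ds$U); S <- as.matrix(ds$S)
  for (i in 1:2)
    expect_equal(coef(f1, "A")[i, -i], oracle_gene_fit(S, U, i)[-1],
                 tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("estimation error shrinks as the cell count grows", {
  A_star <- matrix(c(0, 0.5, -0.4, 0), 2, 2, byrow = TRUE)
  err <- sapply(c(100, 1000), function(n) {
    ds <- make_linear_dataset(n, A_star, noise_sd = 2, seed = 5)
    max(abs(coef(splice_fit(ds, method = "linear", nboot = 1, frac = 1),
                 "A") - A_star))
  })
  expect_lt(err[2], err[1])
})

test_that("seeded subsampling is reproducible and seeds differ", {
  A_star <- matrix(c(0, 0.2, -0.5, 0), 2, 2, byrow = TRUE)
  ds <- make_linear_dataset(60, A_star, noise_sd = 1, seed = 8)
  f1 <- splice_fit(ds, nboot = 5, frac = 0.7, seed = 4, method = "linear")
  f2 <- splice_fit(ds, nboot = 5, frac = 0.7, seed = 4, method = "linear")
  f3 <- splice_fit(ds, nboot = 5, frac = 0.7, seed = 5, method = "linear")
  expect_identical(coef(f1, "A"), coef(f2, "A"))
  expect_false(identical(coef(f1, "A"), coef(f3, "A")))
})

test_that("collinear genes warn under linear and stay finite under ridge", {
  set.seed(2)
  S <- matrix(runif(50 * 2, 1, 5), 50, 2)
  S <- cbind(S, 2 * S[, 2])          # gene 3 = 2 x gene 2
  U <- matrix(runif(50 * 3, 1, 5), 50, 3)
  ds <- splice_dataset(U, S, rep("A", 50), gene_names = paste0("g", 1:3))
  expect_warning(fit <- splice_fit(ds, method = "linear", nboot = 1,
                                   frac = 1), "collinear")
  expect_true(all(is.finite(coef(fit, "A"))))
  expect_silent(fitr <- splice_fit(ds, method = "ridge", lambda = 1,
                                   nboot = 1, frac = 1))
  expect_true(all(is.finite(coef(fitr, "A"))))
})

test_that("lasso shrinks with lambda and reaches zero coefficients", {
  A_star <- matrix(c(0, 0.5, 0, 0.3, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  ds <- make_linear_dataset(80, A_star, noise_sd = 0.2, seed = 6)
  small <- splice_fit(ds, method = "lasso", lambda = 0.1, nboot = 1, frac = 1)
  big <- splice_fit(ds, method = "lasso", lambda = 5000, nboot = 1, frac = 1)
  expect_lt(sum(abs(coef(big, "A"))), sum(abs(coef(small, "A"))))
  expect_gt(sum(coef(big, "A") == 0), sum(coef(small, "A") == 0))
  expect_error(splice_fit(ds, method = "ridge", lambda = -1), "lambda")
})

test_that("the gene checkpoint blocks underdetermined fits", {
  A_star <- matrix(0, 6, 6)
  ds <- make_linear_dataset(5, A_star, A0 = rep(1, 6))
  expect_error(splice_fit(ds, method = "linear"), "max_genes_checkpoint")
})

test_that("predict and residuals reproduce the fitted regression", {
  A_star <- matrix(c(0, 0.5, -0.3, 0), 2, 2, byrow = TRUE)
  ds <- make_linear_dataset(40, A_star, A0 = c(2, 2))
  fit <- splice_fit(ds, method = "linear", nboot = 1, frac = 1)
  expect_lt(max(abs(residuals(fit, ds, "A"))), 1e-8)
  Uhat <- predict(fit, "A", newdata = ds)
  expect_equal(Uhat, as.matrix(ds$U), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("jacobian assembly follows the block convention", {
  m <- structure(list(A = matrix(0, 1, 1,
                                 dimnames = list("g1", "g1")),
                      A0 = c(g1 = 1), gamma = c(g1 = 1), beta = 1,
                      state = "A", meta = list()),
                 class = "state_linear_model")
  J <- assemble_jacobian(m)
  expect_equal(unclass(J), matrix(c(-1, 1, 0, -1), 2, 2),
               ignore_attr = TRUE)
  expect_equal(sort(Re(eigen(unclass(J))$values)), c(-1, -1))

  A <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  J2 <- splicing_jacobian(A, gamma = c(1, 1), beta = 1)
  expect_equal(dim(J2), c(4L, 4L))
  ev <- sort(Re(eigen(unclass(J2))$values))
  # block reduction: lambda = -1 +/- sqrt(mu) for mu in {-1, +1}
  expect_equal(ev, c(-2, -1, -1, 0), tolerance = 1e-12)
  im <- sort(Im(eigen(unclass(J2))$values))
  expect_equal(im, c(-1, 0, 0, 1), tolerance = 1e-12)
  expect_error(splicing_jacobian(matrix(1, 2, 2), c(1, 1)), "diagonal")
  expect_error(splicing_jacobian(A, c(1, -1)), "gamma")
})

test_that("optional library-size normalization rescales cells", {
  ds <- make_toy_dataset()
  fit <- splice_fit(ds[, 1:2], method = "ridge", lambda = 1, nboot = 1,
                    frac = 1, normalize_library = TRUE)
  expect_true(all(is.finite(coef(fit, "A"))))
})
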