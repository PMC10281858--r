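test_that("null REML matches the closed form and a 1-D grid oracle", {
  set.seed(41)
  n <- 40
  Xf <- cbind(1, rnorm(n))
  y <- drop(Xf %*% c(2, -1)) + rnorm(n, sd = 0.7)
  fit <- reml_fit_null(y, Xf)
  qx <- qr(Xf)
  rss <- sum(qr.resid(qx, y)^2)
  expect_equal(fit$sigma_e2, rss / (n - 2), tolerance = 1e-12)
  expect_equal(fit$sigma_s2, 0)
  oracle <- oracle_reml_null_grid(y, Xf)
  expect_equal(fit$restricted_ll, oracle$ll, tolerance = 1e-4)
  expect_equal(fit$sigma_e2, 10^oracle$arg, tolerance = 1e-2)
})

test_that("a perfectly explained response is a degenerate null fit", {
  Xf <- cbind(1, 1:10)
  y <- drop(Xf %*% c(3, 2))
  expect_error(reml_fit_null(y, Xf), "degenerate")
})

test_that("the null residual variance is consistent at large n", {
  set.seed(42)
  y <- rnorm(1000)
  fit <- reml_fit_null(y, matrix(1, 1000, 1))
  expect_lt(abs(fit$sigma_e2 - 1), 0.15)
})

test_that("alternative REML matches the dense 2-D grid oracle on random
           12-sample problems", {
  set.seed(43)
  worst <- 0
  for (i in 1:50) {
    n <- 12
    L <- scale(random_design(n, sample(2:4, 1)))
    Kt <- normalize_kernel(compute_kernel(L, sample(c("linear", "poly"), 1)))
    # half the problems carry real set signal, half pure noise
    y <- if (i %% 2) {
      drop(L %*% rnorm(ncol(L), sd = 1.2)) + rnorm(n)
    } else {
      rnorm(n)
    }
    Xf <- matrix(1, n, 1)
    fit <- reml_fit_alt(y, Xf, Kt)
    oracle <- oracle_reml_alt_grid(y, Xf, Kt$values)
    gap <- abs(fit$restricted_ll - oracle$ll)
    # optimizer must never fall below the grid, and the grid is fine enough
    # to certify the optimum to 1e-3
    expect_gte(fit$restricted_ll, oracle$ll - 1e-6)
    worst <- max(worst, gap)
    expect_lt(gap, 1e-3)
  }
})

test_that("an identity kernel is non-identified and yields a zero statistic", {
  set.seed(44)
  y <- rnorm(25)
  Xf <- matrix(1, 25, 1)
  KI <- structure(list(values = diag(25), kind = "linear", normalized = TRUE),
                  class = "kernel_matrix")
  fit_alt <- reml_fit_alt(y, Xf, KI)
  fit_null <- reml_fit_null(y, Xf)
  expect_equal(fit_alt$restricted_ll, fit_null$restricted_ll, tolerance = 1e-8)
  expect_equal(lrt_statistic(fit_alt, fit_null)$t, 0)
})

test_that("under pure noise the set variance hits the boundary in a
           plurality of draws", {
  set.seed(45)
  zeros <- 0
  reps <- 40
  for (i in seq_len(reps)) {
    L <- scale(random_design(30, 5))
    Kt <- normalize_kernel(compute_kernel(L, "linear"))
    fit <- reml_fit_alt(rnorm(30), matrix(1, 30, 1), Kt)
    zeros <- zeros + (fit$sigma_s2 == 0)
  }
  expect_gte(zeros / reps, 0.35)
})

test_that("the alternative never falls below the nested null", {
  set.seed(46)
  for (i in 1:20) {
    n <- sample(15:40, 1)
    L <- scale(random_design(n, sample(2:6, 1)))
    Kt <- normalize_kernel(compute_kernel(L, "linear"))
    y <- rnorm(n)
    Xf <- matrix(1, n, 1)
    fit_alt <- reml_fit_alt(y, Xf, Kt)
    fit_null <- reml_fit_null(y, Xf)
    expect_gte(fit_alt$restricted_ll, fit_null$restricted_ll - 1e-8)
    expect_gte(lrt_statistic(fit_alt, fit_null)$t, 0)
  }
})

test_that("the statistic is twice the restricted log-likelihood gap, clipped", {
  f <- function(ll) new_fit <- structure(
    list(sigma_s2 = 0.1, sigma_e2 = 1, beta_f = 0, restricted_ll = ll,
         converged = TRUE, delta = 10), class = "lmm_fit")
  expect_equal(lrt_statistic(f(-10), f(-10))$t, 0)
  expect_equal(lrt_statistic(f(-8.7), f(-10))$t, 2.6)
  expect_equal(lrt_statistic(f(-10 - 1e-9), f(-10))$t, 0)  # boundary clip
})

test_that("low-rank and dense spectral paths agree", {
  set.seed(47)
  L <- scale(random_design(20, 4))
  y <- drop(L %*% rnorm(4)) + rnorm(20)
  Xf <- matrix(1, 20, 1)
  Kt <- normalize_kernel(compute_kernel(L, "linear"))
  fit_fast <- reml_fit_alt(y, Xf, Kt)
  Kdense <- Kt
  attr(Kdense, "factor") <- NULL
  fit_dense <- reml_fit_alt(y, Xf, Kdense)
  expect_equal(fit_fast$restricted_ll, fit_dense$restricted_ll,
               tolerance = 1e-6)
  expect_equal(fit_fast$sigma_s2, fit_dense$sigma_s2, tolerance = 1e-4)
})
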