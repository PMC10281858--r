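# REML fits for the set-test linear mixed model
#
#   y = Xf b + g + e,   g ~ N(0, sigma_s^2 K),  e ~ N(0, sigma_e^2 I)
#
# The alternative model's covariance sigma_s^2 K + sigma_e^2 I is profiled
# over the variance ratio delta = sigma_e^2 / sigma_s^2: the kernel is
# eigendecomposed once, y and Xf are rotated into the eigenbasis, and for a
# given delta both sigma^2 and the fixed effects have closed forms, leaving
# a 1-D maximization of the restricted likelihood over log10(delta).  The
# null model (sigma_s^2 = 0) is ordinary least squares with the closed-form
# REML residual variance.  Per-set cost is O(n ns^2) for the linear kernel
# (eigen work on the ns-dimensional Gram factor) and O(n^3) otherwise.
#
# Restricted log-likelihood convention (Harville): for V = Cov(y),
#   ll_R = -1/2 [ log|V| + log|Xf' V^-1 Xf| + (y-Xb)' V^-1 (y-Xb)
#                 + (n-nf) log 2pi - log|Xf'Xf| ],
# identical in the null and alternative fits, so the constant terms cancel
# in the likelihood ratio.

new_lmm_fit <- function(sigma_s2, sigma_e2, beta_f, restricted_ll, converged,
                        delta = NA_real_) {
  structure(list(sigma_s2 = sigma_s2, sigma_e2 = sigma_e2,
                 beta_f = as.numeric(beta_f), restricted_ll = restricted_ll,
                 converged = converged, delta = delta),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("lmm_fit: sigma_s2 = %.4g, sigma_e2 = %.4g, restricted LL = %.4f\n",
              x$sigma_s2, x$sigma_e2, x$restricted_ll))
  invisible(x)
}

#' REML fit of the null model (no set effect)
#'
#' Ordinary least squares for the fixed effects with the REML residual
#' variance `RSS / (n - nf)`.
#'
#' @param y numeric response (finite).
#' @param Xf fixed-effect design matrix (full column rank, `n > nf`);
#'   typically an intercept column plus optional covariates such as
#'   principal components of the genotype matrix.
#' @return an `lmm_fit` with `sigma_s2 = 0`.
#' @export
reml_fit_null <- function(y, Xf) {
  Xf <- as.matrix(Xf)
  n <- length(y)
  nf <- ncol(Xf)
  stopifnot(all(is.finite(y)), n > nf)
  qx <- qr(Xf)
  if (qx$rank < nf) stop("Xf is rank deficient")
  beta <- qr.coef(qx, y)
  rss <- sum(qr.resid(qx, y)^2)
  if (rss <= max(1e-12 * sum(y^2), 0)) {
    stop("degenerate null fit: the fixed effects explain y exactly (zero residual variance)")
  }
  s2 <- rss / (n - nf)
  ll <- -0.5 * ((n - nf) * (log(s2) + 1 + log(2 * pi)))
  new_lmm_fit(0, s2, beta, ll, TRUE, delta = Inf)
}

# spectral pieces of a kernel: eigenvalues `s` (descending, >= 0, only the
# numerically nonzero ones) and the matching orthonormal columns U1; the
# orthogonal complement has eigenvalue exactly 0
kernel_spectrum <- function(K) {
  A <- attr(K, "factor")
  values <- if (inherits(K, "kernel_matrix")) K$values else as.matrix(K)
  n <- nrow(values)
  if (!is.null(A) && ncol(A) < n) {
    e <- eigen(crossprod(A), symmetric = TRUE)
    keep <- e$values > max(e$values, 0) * 1e-12
    if (!any(keep)) return(NULL)
    s <- e$values[keep]
    U1 <- A %*% sweep(e$vectors[, keep, drop = FALSE], 2, sqrt(s), "/")
  } else {
    e <- eigen(values, symmetric = TRUE)
    keep <- e$values > max(e$values, 0) * 1e-12
    if (!any(keep)) return(NULL)
    s <- e$values[keep]
    U1 <- e$vectors[, keep, drop = FALSE]
  }
  list(s = s, U1 = U1, n = n)
}

#' REML fit of the alternative model (set variance component)
#'
#' Maximizes the restricted likelihood of `y ~ N(Xf b, sigma_s^2 K +
#' sigma_e^2 I)` over `sigma_s^2 >= 0`, `sigma_e^2 > 0` by a grid-plus-Brent
#' search on `log10(delta)`, `delta = sigma_e^2/sigma_s^2`, together with an
#' explicit evaluation of the `sigma_s^2 = 0` boundary.  Ties against the
#' boundary are resolved toward the null, so the fit never reports a
#' spurious positive set variance.
#'
#' @inheritParams reml_fit_null
#' @param K a `kernel_matrix` (normalized, see [normalize_kernel()]) or a
#'   plain symmetric PSD matrix.
#' @param delta_log10_range search range for log10(delta).
#' @param tol absolute tolerance of the 1-D search on log10(delta).
#' @param grid_points coarse-grid size used to bracket the global maximum
#'   before the local Brent refinement (the restricted-likelihood profile
#'   can be multimodal in delta).
#' @return an `lmm_fit`; `delta` is `Inf` when the boundary wins.
#' @export
reml_fit_alt <- function(y, Xf, K, delta_log10_range = c(-8, 8), tol = 1e-6,
                         grid_points = 21L) {
  Xf <- as.matrix(Xf)
  n <- length(y)
  nf <- ncol(Xf)
  stopifnot(all(is.finite(y)), n > nf)
  null_fit <- reml_fit_null(y, Xf)
  sp <- kernel_spectrum(K)
  if (is.null(sp)) {
    stop(structure(class = c("ppigwas_untestable", "error", "condition"),
                   list(message = "kernel is numerically zero; neighborhood untestable",
                        call = sys.call())))
  }
  s <- sp$s
  U1 <- sp$U1
  r <- length(s)
  U1y <- drop(crossprod(U1, y))
  U1X <- crossprod(U1, Xf)
  XtX <- crossprod(Xf)
  Xty <- drop(crossprod(Xf, y))
  yty <- sum(y^2)
  ldXX <- as.numeric(determinant(XtX)$modulus)
  cst <- (n - nf) * (1 + log(2 * pi)) - ldXX

  profile_ll <- function(log10_delta) {
    d <- 10^log10_delta
    w <- s + d
    a <- 1 / w - 1 / d
    M <- crossprod(U1X, U1X * a) + XtX / d
    v <- drop(crossprod(U1X, U1y * a)) + Xty / d
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    b <- backsolve(ch, forwardsolve(t(ch), v))
    yWy <- sum(U1y^2 * a) + yty / d
    q <- yWy - 2 * sum(b * v) + sum(b * (M %*% b))
    if (!is.finite(q) || q <= 0) return(list(ll = -Inf))
    s2 <- q / (n - nf)
    ll <- -0.5 * ((n - nf) * log(s2) + sum(log(w)) + (n - r) * log(d) +
                  2 * sum(log(diag(ch))) + cst)
    list(ll = ll, s2 = s2, b = b)
  }

  grid <- seq(delta_log10_range[1], delta_log10_range[2],
              length.out = grid_points)
  grid_ll <- vapply(grid, function(g) profile_ll(g)$ll, numeric(1))
  if (all(!is.finite(grid_ll))) {
    stop(structure(class = c("ppigwas_numerical", "error", "condition"),
                   list(message = "restricted likelihood non-finite across the delta grid",
                        call = sys.call())))
  }
  i <- which.max(grid_ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(function(g) profile_ll(g)$ll, c(lo, hi), maximum = TRUE,
                  tol = tol)
  best <- if (opt$objective >= grid_ll[i]) opt$maximum else grid[i]
  fit <- profile_ll(best)
  if (!is.finite(fit$ll)) {
    stop(structure(class = c("ppigwas_numerical", "error", "condition"),
                   list(message = "restricted likelihood non-finite at the optimum",
                        call = sys.call())))
  }
  # ties against the boundary are resolved toward the null; the 1e-6 slack
  # absorbs roundoff of the spectral profile when the kernel is (nearly)
  # non-identified, e.g. K proportional to I
  if (fit$ll <= null_fit$restricted_ll + 1e-6) {
    # boundary sigma_s^2 = 0 wins (or ties): report the null solution
    return(new_lmm_fit(0, null_fit$sigma_e2, null_fit$beta_f,
                       null_fit$restricted_ll, TRUE, delta = Inf))
  }
  delta <- 10^best
  new_lmm_fit(fit$s2, delta * fit$s2, fit$b, fit$ll, TRUE, delta = delta)
}

#' Likelihood-ratio set statistic
#'
#' `t = max(0, 2 (ll_alt - ll_null))`.  The factor 2 is a convention; the
#' null distribution is empirical and undergoes the identical transform, so
#' only the clip at the boundary matters.
#'
#' @param fit_alt,fit_null `lmm_fit`s from [reml_fit_alt()] and
#'   [reml_fit_null()] on the same `(y, Xf)`.
#' @param gene_id,ns optional bookkeeping carried into the result.
#' @return object of class `set_statistic`: list with `gene_id`, `t`, `ns`.
#' @export
lrt_statistic <- function(fit_alt, fit_null, gene_id = NA_character_,
                          ns = NA_integer_) {
  stopifnot(isTRUE(fit_alt$converged), isTRUE(fit_null$converged))
  t <- max(0, 2 * (fit_alt$restricted_ll - fit_null$restricted_ll))
  structure(list(gene_id = gene_id, t = t, ns = ns), class = "set_statistic")
}

#' One-shot set test for a single neighborhood design
#'
#' Convenience wrapper: kernel, normalization, alternative and null REML
#' fits, likelihood-ratio statistic.
#'
#' @inheritParams reml_fit_null
#' @param L design matrix from [build_design()].
#' @param kernel `"linear"` or `"poly"`.
#' @param null_fit optional precomputed [reml_fit_null()] result (shared
#'   across neighborhoods for a fixed trait).
#' @param gene_id bookkeeping label.
#' @return list with `statistic` (a `set_statistic`), `fit_alt`, `fit_null`.
#' @export
set_lmm_test <- function(y, Xf, L, kernel = c("linear", "poly"),
                         null_fit = NULL, gene_id = NA_character_) {
  kernel <- match.arg(kernel)
  if (is.null(null_fit)) null_fit <- reml_fit_null(y, Xf)
  Kt <- normalize_kernel(compute_kernel(L, kernel))
  fit_alt <- reml_fit_alt(y, Xf, Kt)
  list(statistic = lrt_statistic(fit_alt, null_fit, gene_id = gene_id,
                                 ns = ncol(L)),
       fit_alt = fit_alt, fit_null = null_fit)
}
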