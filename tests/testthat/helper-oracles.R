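# Independent oracles and small fixture builders shared across test files.

# Restricted log-likelihood from first principles: dense covariance algebra,
# no eigen-profiling (Harville convention, matching the package's constant).
oracle_restricted_ll <- function(y, X, V) {
  n <- length(y)
  nf <- ncol(X)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  q <- drop(t(r) %*% Vi %*% r)
  -0.5 * (as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XtViX)$modulus) + q +
            (n - nf) * log(2 * pi) -
            as.numeric(determinant(t(X) %*% X)$modulus))
}

# Brute-force REML of the alternative model: two-stage grid over
# (log10 sigma_s^2, log10 sigma_e^2), refined around the coarse argmax.
oracle_reml_alt_grid <- function(y, X, K, span = c(-4, 2), coarse = 50L,
                                 fine = 60L) {
  eval_grid <- function(ls_vals, le_vals) {
    best <- -Inf
    for (ls in ls_vals) {
      for (le in le_vals) {
        V <- 10^ls * K + 10^le * diag(length(y))
        ll <- tryCatch(oracle_restricted_ll(y, X, V), error = function(e) -Inf)
        if (is.finite(ll) && ll > best) {
          best <- ll
          arg <- c(ls, le)
        }
      }
    }
    list(ll = best, arg = arg)
  }
  g1 <- seq(span[1], span[2], length.out = coarse)
  c1 <- eval_grid(g1, g1)
  step <- diff(g1[1:2])
  g2s <- seq(c1$arg[1] - 2 * step, c1$arg[1] + 2 * step, length.out = fine)
  g2e <- seq(c1$arg[2] - 2 * step, c1$arg[2] + 2 * step, length.out = fine)
  c2 <- eval_grid(g2s, g2e)
  # the boundary sigma_s^2 = 0 is part of the alternative's parameter space
  ols <- oracle_reml_null_grid(y, X)
  if (ols$ll > c2$ll) ols else c2
}

# Brute-force REML of the null model via a 1-D grid on log10 sigma_e^2.
oracle_reml_null_grid <- function(y, X, span = c(-4, 2), coarse = 60L,
                                  fine = 60L) {
  eval_grid <- function(vals) {
    lls <- vapply(vals, function(le) {
      oracle_restricted_ll(y, X, 10^le * diag(length(y)))
    }, numeric(1))
    i <- which.max(lls)
    list(ll = lls[i], arg = vals[i])
  }
  c1 <- eval_grid(seq(span[1], span[2], length.out = coarse))
  step <- diff(seq(span[1], span[2], length.out = coarse)[1:2])
  eval_grid(seq(c1$arg - step, c1$arg + step, length.out = fine))
}

# brute-force kernel: explicit double loop over sample pairs
oracle_kernel <- function(L, kind) {
  n <- nrow(L)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ip <- sum(L[i, ] * L[j, ])
      K[i, j] <- if (kind == "linear") ip else (1 + ip)^2
    }
  }
  K
}

# tiny deterministic genotype fixture: 3 samples x 4 SNPs on two chromosomes
tiny_dataset <- function() {
  genotype_dataset(
    dosages = rbind(c(0, 1, 2, 0), c(1, 1, 0, 2), c(2, 0, 1, 1)),
    snp_ids = c("s1", "s2", "s3", "s4"),
    chrom = c("1", "1", "2", "2"),
    pos = c(100L, 200L, 50L, 150L),
    sample_ids = c("a", "b", "c")
  )
}

# path network g1 - g2 - g3 with one extra isolated gene g4
path_network <- function() {
  gene_network(rbind(c("g1", "g2"), c("g2", "g3")), nodes = "g4")
}

# random genotype matrix with polymorphic columns (for kernel/REML tests)
random_design <- function(n, ns) {
  repeat {
    L <- matrix(rbinom(n * ns, 2, runif(1, 0.2, 0.5)), n, ns)
    if (all(apply(L, 2, sd) > 0)) return(L)
  }
}

# small simulated study used by several files (kept tiny for speed)
small_study <- function(seed = 404, ...) {
  set.seed(seed)
  simulate_study(scenario_config(n = 60, p = 80, ng = 10, ncg = 2,
                                 rcn = 0.5, block_size = 5, ...))
}
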