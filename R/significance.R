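# Empirical significance: the null distribution of the set statistic is the
# pool of statistics recomputed under joint circular SNP rotation and
# degree-preserving network permutation; p-values are pool tail
# probabilities with a pseudocount, followed by multiple-testing control
# across neighborhoods (and, for several traits, a two-level hierarchical
# procedure).

#' Build the pooled permutation null
#'
#' For each permutation index m = 1..np, one fresh circular rotation (offset
#' drawn without replacement by [sample_rotations()]) and one fresh
#' degree-preserving network permutation are applied jointly; all
#' neighborhoods are recomputed on the permuted network, each testable one is
#' refit (alternative vs null REML), and the resulting statistics are pooled
#' flat across neighborhoods and permutations.  Sample rows of y, Xf and the
#' genotypes are never permuted, so relatedness and population structure are
#' preserved under the null.
#'
#' @param dataset a [genotype_dataset()] (rows already aligned with `y`).
#' @param network a [gene_network()].
#' @param slot_map a [map_snps_to_genes()] result.
#' @param y numeric trait.
#' @param Xf fixed-effect matrix.
#' @param np number of permutations.
#' @param k neighborhood hop count.
#' @param kernel `"linear"` or `"poly"`.
#' @param fraction edge-rearrangement target for [permute_network()].
#' @param standardize passed to [build_design()].
#' @param genes genes to use as neighborhood centers (default: all network
#'   nodes, of which only the testable ones contribute).
#' @return object of class `null_pool`: list with `stats` (numeric vector of
#'   pooled statistics), `manifest` (data.frame: `perm_index`, `rotation`,
#'   `network_seed`), `np`, `n_failures`.
#' @export
build_null_pool <- function(dataset, network, slot_map, y, Xf, np = 100L,
                            k = 1L, kernel = "linear", fraction = 0.5,
                            standardize = TRUE, genes = NULL) {
  stopifnot(np >= 1L)
  if (is.null(genes)) genes <- network$nodes
  slots <- participating_slots(slot_map)
  rotations <- sample_rotations(np, length(slots))
  net_seeds <- sample.int(.Machine$integer.max - 1L, np)
  null_fit <- reml_fit_null(y, Xf)
  stats <- vector("list", np)
  n_fail <- 0L
  for (m in seq_len(np)) {
    assignment <- rotate_assignment(slots, rotations[m], slot_map$p)
    set.seed(net_seeds[m])
    net_m <- suppressWarnings(permute_network(network, fraction))
    t_m <- rep(NA_real_, length(genes))
    for (gi in seq_along(genes)) {
      features <- aggregate_neighborhood(genes[gi], net_m, slot_map, k)
      if (features$ns == 0L) next
      t_m[gi] <- tryCatch({
        L <- build_design(features, dataset, assignment, standardize)
        set_lmm_test(y, Xf, L, kernel, null_fit = null_fit,
                     gene_id = genes[gi])$statistic$t
      },
      ppigwas_untestable = function(e) NA_real_,
      ppigwas_numerical = function(e) {
        message("numerical failure in permutation ", m, ", gene ", genes[gi])
        n_fail <<- n_fail + 1L
        NA_real_
      })
    }
    if (all(is.na(t_m))) stop("permutation ", m, " produced no testable neighborhood")
    stats[[m]] <- t_m[!is.na(t_m)]
  }
  structure(list(stats = unlist(stats, use.names = FALSE),
                 manifest = data.frame(perm_index = seq_len(np),
                                       rotation = rotations,
                                       network_seed = net_seeds),
                 np = np, n_failures = n_fail),
            class = "null_pool")
}

#' @export
print.null_pool <- function(x, ...) {
  cat(sprintf("null_pool: %d statistics from %d permutation(s)%s\n",
              length(x$stats), x$np,
              if (x$n_failures) sprintf(" (%d numerical failures)", x$n_failures) else ""))
  invisible(x)
}

#' Empirical p-value against a permutation pool
#'
#' `p = (pseudocount + #\{t0 in pool : t0 >= t\}) / (pseudocount + |pool|)`.
#' Ties count toward the null (conservative); with the default pseudocount 1
#' the p-value is bounded below by `1/(|pool|+1)` and can never be zero.
#'
#' @param t statistic value(s) (numeric vector or a `set_statistic`).
#' @param pool a `null_pool` or numeric vector of null statistics.
#' @param pseudocount non-negative; default 1.
#' @return numeric vector of p-values in (0, 1].
#' @export
empirical_pvalue <- function(t, pool, pseudocount = 1) {
  if (inherits(t, "set_statistic")) t <- t$t
  stats <- if (inherits(pool, "null_pool")) pool$stats else as.numeric(pool)
  stopifnot(length(stats) >= 1L, pseudocount >= 0)
  n0 <- length(stats)
  sorted <- sort(stats)
  # #{t0 >= t} via binary search on the sorted pool
  n_ge <- n0 - findInterval(t, sorted, left.open = TRUE)
  (pseudocount + n_ge) / (pseudocount + n0)
}

#' Benjamini-Hochberg step-up procedure
#'
#' @param pvalues numeric vector in (0, 1]; `NA`s allowed (never rejected).
#' @param alpha FDR level.
#' @return list with `adjusted` (BH-adjusted p-values) and `rejected`
#'   (logical).
#' @export
bh_procedure <- function(pvalues, alpha = 0.05) {
  adjusted <- p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted,
       rejected = !is.na(adjusted) & adjusted <= alpha)
}

# Simes combination of a set of p-values: min_i m p_(i) / i
simes_pvalue <- function(p) {
  p <- sort(p[!is.na(p)])
  if (!length(p)) return(NA_real_)
  min(1, min(length(p) * p / seq_along(p)))
}

#' Two-level hierarchical FDR control across traits and neighborhoods
#'
#' Stage 1 combines each trait's neighborhood p-values into one global
#' trait-level p-value by Simes' method and applies Benjamini-Hochberg
#' across the T traits at level `alpha`.  Stage 2 applies
#' Benjamini-Hochberg within each selected trait across its neighborhoods at
#' the reduced level `alpha * R / T`, where R is the number of selected
#' traits.  With a single trait the procedure reduces exactly to
#' [bh_procedure()] at level `alpha`.
#'
#' @param pvalue_matrix numeric matrix, traits in rows, neighborhoods
#'   (genes) in columns; `NA` entries allowed.
#' @param alpha target FDR level.
#' @return list with `significant` (logical matrix, same shape),
#'   `trait_pvalues` (Simes p per trait), `selected_traits` (logical).
#' @export
hierarchical_fdr <- function(pvalue_matrix, alpha = 0.05) {
  pm <- as.matrix(pvalue_matrix)
  trait_p <- apply(pm, 1, simes_pvalue)
  sel <- bh_procedure(trait_p, alpha)$rejected
  R <- sum(sel, na.rm = TRUE)
  Tn <- nrow(pm)
  sig <- matrix(FALSE, nrow(pm), ncol(pm), dimnames = dimnames(pm))
  if (R > 0L) {
    level2 <- alpha * R / Tn
    for (i in which(sel)) {
      sig[i, ] <- bh_procedure(pm[i, ], level2)$rejected
    }
  }
  list(significant = sig, trait_pvalues = trait_p, selected_traits = sel)
}
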