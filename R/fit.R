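# Main fitting interface: one call runs the whole method — neighborhood
# aggregation, observed set statistics, the two-level permutation null,
# empirical p-values and FDR control — and returns a classed result.

# observed (or permuted) statistics for all center genes with >= 1 slot
compute_set_statistics <- function(dataset, network, slot_map, y, Xf,
                                   k = 1L, kernel = "linear",
                                   assignment = NULL, standardize = TRUE,
                                   null_fit = NULL) {
  if (is.null(null_fit)) null_fit <- reml_fit_null(y, Xf)
  genes <- network$nodes
  rows <- lapply(genes, function(g) {
    features <- aggregate_neighborhood(g, network, slot_map, k)
    if (features$ns == 0L) return(NULL)
    t <- tryCatch({
      L <- build_design(features, dataset, assignment, standardize)
      set_lmm_test(y, Xf, L, kernel, null_fit = null_fit,
                   gene_id = g)$statistic$t
    },
    ppigwas_untestable = function(e) NA_real_,
    ppigwas_numerical = function(e) {
      message("numerical failure for gene ", g)
      NA_real_
    })
    data.frame(gene_id = g, n_snps_in_neighborhood = features$ns,
               lrt_statistic = t, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Network-guided SNP-set association study
#'
#' Tests, for every gene in the network that has at least one SNP in its
#' k-hop neighborhood, whether that neighborhood's SNPs are associated with
#' the trait.  Per neighborhood the SNPs enter a linear mixed model as a
#' random effect with a normalized linear or polynomial kernel and
#' association is the restricted-likelihood ratio against the no-set-effect
#' null.  The null distribution is empirical: `np` joint permutations
#' (circular SNP rotation over fixed genomic coordinates + degree-preserving
#' network permutation) are applied, every neighborhood is refit under each,
#' and all `ng x np` statistics are pooled.  Benjamini-Hochberg control is
#' applied across neighborhoods at level `alpha`.
#'
#' @param genotypes a [genotype_dataset()].
#' @param network a [gene_network()] (or a 2-column edge matrix).
#' @param annotation gene annotation data.frame (`gene_id`, `chrom`,
#'   `start`, `end`, 1-based inclusive).
#' @param phenotypes phenotype data.frame (`sample_id` + trait columns) or a
#'   named numeric vector.
#' @param trait trait column to analyse (default: first).
#' @param covariates optional data.frame (`sample_id` + numeric columns)
#'   entering as fixed effects next to the intercept.
#' @param k neighborhood hop count (default 1).
#' @param kernel `"linear"` or `"poly"`.
#' @param np number of permutations for the null pool.
#' @param fraction edge-rearrangement target of the network permutation.
#' @param pseudocount pseudocount of the empirical p-value.
#' @param alpha FDR level.
#' @param standardize center/scale SNP columns before the kernel.
#' @param seed integer; seeds all randomness (rotation draws and network
#'   permutation streams) for exact reproducibility.
#' @return object of class `ppigwas`: list with `results` (data.frame:
#'   `gene_id`, `n_snps_in_neighborhood`, `lrt_statistic`, `pvalue`,
#'   `pvalue_adjusted`, `fdr_significant`), `null_pool`, `null_fit`,
#'   `config`, `n_samples`, `trait`.
#' @seealso [write_results()], [build_null_pool()], [hierarchical_fdr()]
#' @examples
#' \donttest{
#' set.seed(7)
#' study <- simulate_study(scenario_config(n = 80, p = 120, ng = 12, ncg = 3))
#' fit <- ppigwas(study$dataset, study$network, study$annotation,
#'                study$phenotypes, np = 5, seed = 7)
#' print(fit)
#' }
#' @export
ppigwas <- function(genotypes, network, annotation, phenotypes, trait = NULL,
                    covariates = NULL, k = 1L, kernel = c("linear", "poly"),
                    np = 100L, fraction = 0.5, pseudocount = 1,
                    alpha = 0.05, standardize = TRUE, seed = NULL) {
  kernel <- match.arg(kernel)
  stopifnot(k >= 0L, np >= 1L, fraction > 0, fraction <= 1,
            pseudocount >= 0, alpha > 0, alpha < 1)
  if (!inherits(network, "gene_network")) network <- gene_network(network)
  if (is.numeric(phenotypes) && !is.null(names(phenotypes))) {
    phenotypes <- data.frame(sample_id = names(phenotypes),
                             trait = unname(phenotypes),
                             stringsAsFactors = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(trait)) trait <- setdiff(names(phenotypes), "sample_id")[1]

  aligned <- align_samples(genotypes, phenotypes, trait, covariates)
  slot_map <- map_snps_to_genes(aligned$dataset, annotation)
  null_fit <- reml_fit_null(aligned$y, aligned$Xf)

  observed <- compute_set_statistics(aligned$dataset, network, slot_map,
                                     aligned$y, aligned$Xf, k, kernel,
                                     standardize = standardize,
                                     null_fit = null_fit)
  if (is.null(observed) || !nrow(observed)) {
    stop("no testable neighborhood (no gene has SNPs in its k-hop neighborhood)")
  }
  pool <- build_null_pool(aligned$dataset, network, slot_map, aligned$y,
                          aligned$Xf, np = np, k = k, kernel = kernel,
                          fraction = fraction, standardize = standardize)

  results <- observed
  results$pvalue <- NA_real_
  ok <- !is.na(results$lrt_statistic)
  results$pvalue[ok] <- empirical_pvalue(results$lrt_statistic[ok], pool,
                                         pseudocount)
  bh <- bh_procedure(results$pvalue, alpha)
  results$pvalue_adjusted <- bh$adjusted
  results$fdr_significant <- bh$rejected
  results <- results[order(results$gene_id), ]
  rownames(results) <- NULL

  structure(list(results = results, null_pool = pool, null_fit = null_fit,
                 config = list(trait = trait, k = k, kernel = kernel,
                               np = np, fraction = fraction,
                               pseudocount = pseudocount, alpha = alpha,
                               standardize = standardize, seed = seed),
                 n_samples = length(aligned$sample_ids), trait = trait),
            class = "ppigwas")
}

#' @export
print.ppigwas <- function(x, ...) {
  r <- x$results
  cat("Network-guided SNP-set association study\n")
  cat(sprintf("  trait: %s   samples: %d   kernel: %s   k = %d hop(s)\n",
              x$trait, x$n_samples, x$config$kernel, x$config$k))
  cat(sprintf("  %d testable neighborhoods; null pool of %d statistics (%d permutations)\n",
              sum(!is.na(r$lrt_statistic)), length(x$null_pool$stats),
              x$config$np))
  cat(sprintf("  %d neighborhood(s) significant at FDR %.2g\n",
              sum(r$fdr_significant, na.rm = TRUE), x$config$alpha))
  invisible(x)
}

#' @export
summary.ppigwas <- function(object, n_top = 10L, ...) {
  r <- object$results[order(object$results$pvalue,
                            -object$results$lrt_statistic), ]
  structure(list(fit = object, top = head(r, n_top)),
            class = "summary.ppigwas")
}

#' @export
print.summary.ppigwas <- function(x, ...) {
  print(x$fit)
  cat("\nTop neighborhoods:\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Diagnostic plots for a fitted study
#'
#' Left: the pooled permutation null distribution of the set statistic with
#' the observed statistics overlaid.  Right: per-gene `-log10` empirical
#' p-values with the FDR-significant neighborhoods highlighted.
#'
#' @param x a `ppigwas` object.
#' @param ... unused.
#' @export
plot.ppigwas <- function(x, ...) {
  r <- x$results[!is.na(x$results$pvalue), ]
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  hist(x$null_pool$stats, breaks = 40, freq = FALSE, col = "grey85",
       border = "white", main = "Permutation null",
       xlab = "set LRT statistic")
  points(r$lrt_statistic, rep(0, nrow(r)), pch = 3, col = "firebrick")
  legend("topright", legend = c("null pool", "observed"),
         fill = c("grey85", NA), border = NA,
         pch = c(NA, 3), col = c(NA, "firebrick"), bty = "n")
  mlp <- -log10(r$pvalue)
  sig <- r$fdr_significant %in% TRUE
  plot(seq_len(nrow(r)), mlp, pch = 19,
       col = ifelse(sig, "firebrick", adjustcolor("grey30", 0.6)),
       xlab = "gene (alphabetical)", ylab = expression(-log[10](p)),
       main = "Neighborhood significance")
  abline(h = -log10(x$config$alpha), lty = 2)
  invisible(x)
}

#' Multi-trait study with hierarchical FDR control
#'
#' Fits [ppigwas()] per trait (re-seeding so every trait faces the same
#' permutation plan) and controls the FDR jointly across traits and
#' neighborhoods with the two-level procedure of [hierarchical_fdr()].
#'
#' @inheritParams ppigwas
#' @param traits trait column names (default: all non-id columns).
#' @param ... passed on to [ppigwas()].
#' @return object of class `ppigwas_multi`: list with `fits` (per trait),
#'   `pvalue_matrix` (traits x genes), `fdr` (the [hierarchical_fdr()]
#'   result), `significant` (logical matrix).
#' @export
ppigwas_multitrait <- function(genotypes, network, annotation, phenotypes,
                               traits = NULL, alpha = 0.05, seed = NULL, ...) {
  if (is.null(traits)) traits <- setdiff(names(phenotypes), "sample_id")
  fits <- lapply(traits, function(tr) {
    ppigwas(genotypes, network, annotation, phenotypes, trait = tr,
            alpha = alpha, seed = seed, ...)
  })
  names(fits) <- traits
  genes <- sort(unique(unlist(lapply(fits, function(f) f$results$gene_id))))
  pm <- matrix(NA_real_, length(traits), length(genes),
               dimnames = list(traits, genes))
  for (tr in traits) {
    r <- fits[[tr]]$results
    pm[tr, r$gene_id] <- r$pvalue
  }
  fdr <- hierarchical_fdr(pm, alpha)
  structure(list(fits = fits, pvalue_matrix = pm, fdr = fdr,
                 significant = fdr$significant),
            class = "ppigwas_multi")
}

#' @export
print.ppigwas_multi <- function(x, ...) {
  cat(sprintf("Multi-trait study: %d trait(s), %d gene(s)\n",
              nrow(x$pvalue_matrix), ncol(x$pvalue_matrix)))
  cat(sprintf("  selected traits: %s\n",
              paste(rownames(x$pvalue_matrix)[x$fdr$selected_traits],
                    collapse = ", ")))
  cat(sprintf("  %d significant (trait, neighborhood) pair(s)\n",
              sum(x$significant)))
  invisible(x)
}
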