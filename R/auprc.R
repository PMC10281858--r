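# Precision-recall evaluation of a gene ranking against causal-gene labels.

#' Area under the precision-recall curve for a gene ranking
#'
#' Genes are ranked by decreasing score (higher = more associated; pass
#' `-pvalue` or `-log10(pvalue)` for p-value rankings).  The PR step curve
#' is evaluated at distinct score thresholds, so a block of tied genes moves
#' recall and precision jointly — a constant score yields exactly the
#' prevalence, and a perfect ranking yields 1.
#'
#' @param scores_per_gene named numeric vector of association scores.
#' @param causal_genes character vector of true causal gene ids; every one
#'   that is scored counts as a positive.
#' @return the area (scalar in \[0, 1\]); attribute `prevalence` carries the
#'   positive fraction.
#' @export
evaluate_auprc <- function(scores_per_gene, causal_genes) {
  stopifnot(!is.null(names(scores_per_gene)))
  labels <- names(scores_per_gene) %in% causal_genes
  P <- sum(labels)
  if (P == 0L) stop("no causal gene among the scored genes; AUPRC undefined")
  ord <- order(scores_per_gene, decreasing = TRUE)
  sc <- scores_per_gene[ord]
  lb <- labels[ord]
  block_end <- which(!duplicated(sc, fromLast = TRUE))  # last index of each tie block
  tp <- cumsum(lb)[block_end]
  fp <- cumsum(!lb)[block_end]
  d_tp <- diff(c(0, tp))
  precision <- tp / (tp + fp)
  area <- sum((d_tp / P) * precision)
  structure(area, prevalence = P / length(labels))
}
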