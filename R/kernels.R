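# SNP-set kernels.  For a neighborhood with per-sample feature rows l_i the
# linear kernel is the Gram matrix <l_i, l_j> and the polynomial kernel the
# inhomogeneous quadratic (1 + <l_i, l_j>)^2; the final kernel is normalized
# to unit diagonal so that the set-variance component is comparable across
# neighborhoods of different size.

#' Build the per-sample neighborhood design matrix
#'
#' Row i is the feature vector of sample i over the neighborhood's SNP slots,
#' reading each slot through `assignment` (identity for the observed pass, a
#' [rotate_assignment()] vector for permuted passes).  With
#' `standardize = TRUE` (default) columns are centered and scaled to unit
#' variance; monomorphic columns, which carry no information, become all-zero
#' columns.
#'
#' @param features [aggregate_neighborhood()] result.
#' @param dataset a [genotype_dataset()].
#' @param assignment optional integer slot-to-column assignment.
#' @param standardize center/scale columns.
#' @return n x ns numeric matrix.
#' @export
build_design <- function(features, dataset, assignment = NULL,
                         standardize = TRUE) {
  if (features$ns == 0L) {
    stop(structure(class = c("ppigwas_untestable", "error", "condition"),
                   list(message = paste0("neighborhood of ", features$gene_id,
                                         " contains no SNPs"),
                        call = sys.call(-1))))
  }
  cols <- features$snp_slots
  if (!is.null(assignment)) cols <- assignment[cols]
  L <- dataset$dosages[, cols, drop = FALSE]
  storage.mode(L) <- "double"
  if (standardize) {
    mu <- colMeans(L)
    sdev <- sqrt(colMeans(L^2) - mu^2)
    keep <- sdev > 0
    L <- sweep(L, 2, mu, "-")
    L[, !keep] <- 0
    if (any(keep)) L[, keep] <- sweep(L[, keep, drop = FALSE], 2, sdev[keep], "/")
  }
  L
}

#' Compute a SNP-set kernel matrix
#'
#' @param L design matrix from [build_design()].
#' @param kind `"linear"` (`K = L L'`) or `"poly"`
#'   (`K_ij = (1 + <l_i, l_j>)^2`).
#' @return object of class `kernel_matrix`: list with `values` (n x n
#'   symmetric), `kind`, `normalized = FALSE`.  For the linear kind, the
#'   low-rank factor is kept alongside so downstream eigen work can run on
#'   the ns-dimensional Gram instead of the n x n matrix.
#' @export
compute_kernel <- function(L, kind = c("linear", "poly")) {
  kind <- match.arg(kind)
  stopifnot(all(is.finite(L)))
  G <- tcrossprod(L)
  values <- if (kind == "linear") G else (1 + G)^2
  values <- (values + t(values)) / 2
  out <- structure(list(values = values, kind = kind, normalized = FALSE),
                   class = "kernel_matrix")
  if (kind == "linear") attr(out, "factor") <- L
  out
}

#' Normalize a kernel to unit diagonal
#'
#' `K~_ij = K_ij / sqrt(K_ii K_jj)`.  Rows/columns whose raw diagonal is zero
#' (samples with an all-zero feature vector) are set to zero, diagonal
#' included, and recorded in the `zero_diag` attribute.
#'
#' @param K a `kernel_matrix`.
#' @return a `kernel_matrix` with `normalized = TRUE` and diagonal exactly 1
#'   wherever the raw diagonal was positive.
#' @export
normalize_kernel <- function(K) {
  stopifnot(inherits(K, "kernel_matrix"))
  d <- diag(K$values)
  pos <- d > 0
  s <- ifelse(pos, 1 / sqrt(d), 0)
  values <- K$values * outer(s, s)
  diag(values)[pos] <- 1
  out <- structure(list(values = values, kind = K$kind, normalized = TRUE),
                   class = "kernel_matrix")
  f <- attr(K, "factor")
  if (!is.null(f)) attr(out, "factor") <- f * s
  attr(out, "zero_diag") <- which(!pos)
  out
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix: %d x %d, kind = %s, %snormalized\n",
              nrow(x$values), ncol(x$values), x$kind,
              if (x$normalized) "" else "not "))
  invisible(x)
}
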