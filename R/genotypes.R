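# Genotype container: n samples x p SNPs, minor-allele dosages in {0,1,2},
# columns kept in circular genomic order (natural chromosome order, then
# ascending position).  That order is load-bearing: the circular SNP
# rotation of the permutation null walks columns in exactly this order.

#' Natural order of chromosome labels
#'
#' Orders chromosome labels the way a geneticist reads them: numeric labels
#' (with or without a "chr" prefix) ascending numerically first, then
#' non-numeric labels (X, Y, MT, ...) alphabetically.  "10" therefore sorts
#' after "2", unlike lexicographic order.
#'
#' @param labels character vector of chromosome labels.
#' @return integer ranks usable as a sort key; equal labels get equal ranks.
#' @examples
#' order(chrom_rank(c("10", "2", "1", "X")))
#' @export
chrom_rank <- function(labels) {
  labels <- as.character(labels)
  stripped <- sub("^[Cc]hr", "", labels)
  num <- suppressWarnings(as.numeric(stripped))
  lev <- unique(stripped)
  lev_num <- suppressWarnings(as.numeric(lev))
  lev_sorted <- c(
    lev[!is.na(lev_num)][order(lev_num[!is.na(lev_num)])],
    sort(lev[is.na(lev_num)])
  )
  match(stripped, lev_sorted)
}

#' Construct a genotype dataset
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns, values in
#'   \{0,1,2\}.  `NA` is allowed only with `impute_missing = TRUE`.
#' @param snp_ids,chrom,pos per-SNP identifier, chromosome label and 1-based
#'   base-pair position (length `ncol(dosages)`).
#' @param sample_ids per-sample identifiers (length `nrow(dosages)`).
#' @param impute_missing impute missing dosages to the rounded per-SNP mean
#'   (the imputed count is reported via `message()`).
#' @return an object of class `genotype_dataset` with elements `dosages`
#'   (integer matrix, columns sorted genomically), `snp_ids`, `chrom`, `pos`,
#'   `sample_ids`.
#' @export
genotype_dataset <- function(dosages, snp_ids, chrom, pos, sample_ids,
                             impute_missing = FALSE) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  p <- ncol(dosages)
  if (n < 2L) stop("genotype dataset needs at least 2 samples")
  if (p < 1L) stop("genotype dataset needs at least 1 SNP")
  snp_ids <- as.character(snp_ids)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  sample_ids <- as.character(sample_ids)
  stopifnot(length(snp_ids) == p, length(chrom) == p, length(pos) == p,
            length(sample_ids) == n)
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  if (anyDuplicated(paste(chrom, pos, snp_ids))) {
    stop("duplicated (chrom, pos, snp_id) triples")
  }

  if (anyNA(dosages)) {
    if (!impute_missing) stop("missing dosages present; set impute_missing = TRUE")
    n_missing <- sum(is.na(dosages))
    for (j in which(colSums(is.na(dosages)) > 0L)) {
      col <- dosages[, j]
      fill <- if (all(is.na(col))) 0 else round(mean(col, na.rm = TRUE))
      dosages[is.na(col), j] <- fill
    }
    message("imputed ", n_missing, " missing dosages to per-SNP rounded means")
  }
  bad <- which(!(dosages %in% c(0, 1, 2)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% n) + 1L
    j <- ((bad[1] - 1L) %/% n) + 1L
    stop(sprintf("dosage not in {0,1,2} at sample %s (row %d), SNP %s (col %d): %s",
                 sample_ids[i], i, snp_ids[j], j, dosages[i, j]))
  }
  storage.mode(dosages) <- "integer"

  ord <- order(chrom_rank(chrom), pos)        # stable total genomic order
  dosages <- dosages[, ord, drop = FALSE]
  snp_ids <- snp_ids[ord]
  chrom <- chrom[ord]
  pos <- pos[ord]
  dimnames(dosages) <- list(sample_ids, snp_ids)

  structure(
    list(dosages = dosages, snp_ids = snp_ids, chrom = chrom, pos = pos,
         sample_ids = sample_ids),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d SNPs on %d chromosome(s)\n",
              length(x$sample_ids), length(x$snp_ids),
              length(unique(x$chrom))))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosages)

#' Subset a genotype dataset to a set of samples (in the given order)
#'
#' @param dataset a `genotype_dataset`.
#' @param sample_ids character vector, a subset of `dataset$sample_ids`.
#' @return a `genotype_dataset` with rows restricted/reordered.
#' @export
subset_samples <- function(dataset, sample_ids) {
  idx <- match(sample_ids, dataset$sample_ids)
  if (anyNA(idx)) stop("unknown sample ids: ",
                       paste(sample_ids[is.na(idx)], collapse = ", "))
  genotype_dataset(dataset$dosages[idx, , drop = FALSE], dataset$snp_ids,
                   dataset$chrom, dataset$pos, sample_ids)
}
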