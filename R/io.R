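# Readers/writers for every external artifact: genotypes (TSV or PLINK
# .bed/.bim/.fam), gene annotation, PPI edge lists, phenotypes, results.
# All TSV dialects: header row, tab separator, UTF-8.  Coordinates are
# 1-based inclusive throughout (PLINK/GFF convention).

#' Read genotypes from TSV or PLINK bed/bim/fam
#'
#' The TSV layout is one row per SNP with columns `snp_id`, `chrom`, `pos`
#' followed by one dosage column per sample (header row carries sample ids).
#' The PLINK layout is the standard SNP-major binary triplet; `path` is then
#' the prefix (without extension).  Dosages count minor (A1) alleles.
#' Missing dosages (PLINK missing code, or empty/NA cells in TSV) are imputed
#' to the rounded per-SNP mean; any other non-\{0,1,2\} TSV value is a hard
#' error naming the offending row and column.
#'
#' @param path file path (TSV) or PLINK prefix.
#' @param format `"tsv"` or `"plink-bed"`.
#' @return a [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("tsv", "plink-bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- read.delim(path, check.names = FALSE, colClasses = "character")
    need <- c("snp_id", "chrom", "pos")
    if (!all(need %in% names(tab)[1:3])) {
      stop("genotype TSV must start with columns snp_id, chrom, pos")
    }
    sample_ids <- names(tab)[-(1:3)]
    if (!length(sample_ids)) stop("genotype TSV has no sample columns")
    raw <- as.matrix(tab[, -(1:3), drop = FALSE])
    raw[raw %in% c("", "NA")] <- NA
    num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
    bad <- which(!is.na(raw) & (is.na(num) | !(num %in% c(0, 1, 2))))
    if (length(bad)) {
      i <- ((bad[1] - 1L) %% nrow(raw)) + 1L
      j <- ((bad[1] - 1L) %/% nrow(raw)) + 1L
      stop(sprintf("non-{0,1,2} dosage '%s' in %s at data row %d (SNP %s), column %s",
                   raw[i, j], path, i, tab$snp_id[i], sample_ids[j]))
    }
    genotype_dataset(t(num), tab$snp_id, tab$chrom, as.integer(tab$pos),
                     sample_ids, impute_missing = anyNA(num))
  } else {
    read_plink(path)
  }
}

#' Write genotypes to TSV or a PLINK bed/bim/fam triplet
#'
#' @param dataset a [genotype_dataset()].
#' @param path output file (TSV) or PLINK prefix.
#' @param format `"tsv"` or `"plink-bed"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(dataset, path, format = c("tsv", "plink-bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(snp_id = dataset$snp_ids, chrom = dataset$chrom,
                      pos = dataset$pos, t(dataset$dosages),
                      check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write_plink(dataset, path)
  }
  invisible(path)
}

# PLINK SNP-major .bed 2-bit codes, A1 = minor allele:
#   00 -> hom A1 (dosage 2), 10 -> het (1), 11 -> hom A2 (0), 01 -> missing.
.bed_code_for_dosage <- c(`0` = 3L, `1` = 2L, `2` = 0L)

read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing PLINK file: ", f)
  fam_tab <- read.table(fam, colClasses = "character")
  bim_tab <- read.table(bim, colClasses = "character")
  n <- nrow(fam_tab)
  p <- nrow(bim_tab)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b) ||
      raw[3] != as.raw(0x01)) {
    stop(bed, " is not a SNP-major PLINK .bed file")
  }
  bytes_per_snp <- (n + 3L) %/% 4L
  if (length(raw) - 3L != bytes_per_snp * p) {
    stop(sprintf("PLINK triplet inconsistent: %s implies %d samples and %s %d SNPs, but %s has %d data bytes (expected %d)",
                 fam, n, bim, p, bed, length(raw) - 3L, bytes_per_snp * p))
  }
  body <- as.integer(raw[-(1:3)])
  # expand each byte into 4 two-bit codes (sample-minor within byte)
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, (body %/% 64L) %% 4L)
  dim(codes) <- c(4L * bytes_per_snp, p)
  codes <- codes[seq_len(n), , drop = FALSE]
  dosage <- matrix(NA_integer_, n, p)
  dosage[codes == 0L] <- 2L
  dosage[codes == 2L] <- 1L
  dosage[codes == 3L] <- 0L
  genotype_dataset(dosage, bim_tab[[2]], bim_tab[[1]],
                   as.integer(bim_tab[[4]]), fam_tab[[2]],
                   impute_missing = anyNA(dosage))
}

write_plink <- function(dataset, prefix) {
  n <- length(dataset$sample_ids)
  p <- length(dataset$snp_ids)
  fam <- data.frame(dataset$sample_ids, dataset$sample_ids, 0L, 0L, 0L, -9L)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(dataset$chrom, dataset$snp_ids, 0L, dataset$pos, "A", "B")
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  codes <- matrix(.bed_code_for_dosage[as.character(dataset$dosages)], n, p)
  codes[is.na(codes)] <- 1L    # PLINK missing code
  pad <- 4L * ((n + 3L) %/% 4L) - n
  if (pad) codes <- rbind(codes, matrix(0L, pad, p))
  weights <- c(1L, 4L, 16L, 64L)
  dim(codes) <- c(4L, length(codes) %/% 4L)
  bytes <- as.raw(colSums(codes * weights))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  invisible(prefix)
}

#' Read a gene annotation table
#'
#' TSV with header columns `gene_id`, `chrom`, `start`, `end`; intervals are
#' 1-based inclusive.
#'
#' @param path file path.
#' @return a data.frame with those four columns.
#' @export
read_annotation <- function(path) {
  tab <- read.delim(path, colClasses = c("character", "character", "integer",
                                         "integer"))
  names(tab)[1:4] <- c("gene_id", "chrom", "start", "end")
  validate_annotation(tab)
}

validate_annotation <- function(tab) {
  tab <- as.data.frame(tab)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(tab)))
  if (anyDuplicated(tab$gene_id)) stop("duplicated gene_id in annotation")
  if (any(tab$start > tab$end)) stop("annotation has start > end")
  tab
}

#' Read a PPI edge list
#'
#' TSV with two columns of gene ids (header row).  Self-loops are dropped and
#' duplicate/reversed edges collapsed so the result obeys the undirected
#' simple-graph contract; the number of dropped lines is reported via
#' `message()`.  Edges naming genes absent from `annotation` (when given) are
#' kept with a warning — such genes become network nodes with no SNPs.
#'
#' @param path file path.
#' @param annotation optional annotation data.frame used only for the
#'   unknown-gene warning.
#' @return a 2-column character matrix of unique undirected edges.
#' @export
read_network <- function(path, annotation = NULL) {
  tab <- tryCatch(read.delim(path, colClasses = "character"),
                  error = function(e) NULL)
  if (is.null(tab) || !nrow(tab)) {
    return(matrix(character(), 0, 2, dimnames = list(NULL, c("gene_a", "gene_b"))))
  }
  edges <- canonical_edges(as.matrix(tab[, 1:2]))
  n_drop <- nrow(tab) - nrow(edges)
  if (n_drop > 0L) {
    message("dropped ", n_drop, " self-loop/duplicate edge line(s) from ", path)
  }
  if (!is.null(annotation)) {
    unknown <- setdiff(unique(as.vector(edges)), annotation$gene_id)
    if (length(unknown)) {
      warning("network names ", length(unknown),
              " gene(s) absent from the annotation (kept as SNP-less nodes): ",
              paste(head(unknown, 5), collapse = ", "),
              if (length(unknown) > 5) ", ...")
    }
  }
  edges
}

# canonical undirected simple edge matrix: pair-sorted, deduplicated,
# self-loops removed, rows ordered
canonical_edges <- function(edges) {
  if (!length(edges)) {
    return(matrix(character(), 0, 2,
                  dimnames = list(NULL, c("gene_a", "gene_b"))))
  }
  edges <- matrix(as.character(edges), ncol = 2)
  keep <- edges[, 1] != edges[, 2]
  edges <- edges[keep, , drop = FALSE]
  a <- pmin(edges[, 1], edges[, 2])
  b <- pmax(edges[, 1], edges[, 2])
  key <- paste0(a, "\r", b)
  dup <- duplicated(key)
  out <- cbind(gene_a = a[!dup], gene_b = b[!dup])
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Read a phenotype table
#'
#' `"tsv"`: header row, first column `sample_id`, remaining columns one
#' continuous trait each.  `"fam"`: whitespace-separated PLINK .fam/.pheno
#' style without header (FID IID PAT MAT SEX PHENO); the trait is named
#' `"pheno"` and the PLINK missing code -9 becomes `NA`.
#'
#' @param path file path.
#' @param format `"tsv"` or `"fam"`.
#' @return data.frame with `sample_id` plus numeric trait columns.
#' @export
read_phenotypes <- function(path, format = c("tsv", "fam")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- read.delim(path, check.names = FALSE)
    names(tab)[1] <- "sample_id"
    tab$sample_id <- as.character(tab$sample_id)
    for (j in seq_along(tab)[-1]) tab[[j]] <- as.numeric(tab[[j]])
  } else {
    raw <- read.table(path, colClasses = "character")
    y <- as.numeric(raw[[6]])
    y[y == -9] <- NA
    tab <- data.frame(sample_id = raw[[2]], pheno = y,
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(tab$sample_id)) stop("duplicated sample ids in ", path)
  tab
}

#' Write per-neighborhood association results
#'
#' Writes the canonical results TSV with columns `gene_id`,
#' `n_snps_in_neighborhood`, `lrt_statistic`, `pvalue`, `fdr_significant`,
#' rows ordered by `gene_id`.
#'
#' @param results data.frame holding at least those five columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  cols <- c("gene_id", "n_snps_in_neighborhood", "lrt_statistic", "pvalue",
            "fdr_significant")
  if (!nrow(results)) stop("empty results")
  stopifnot(all(cols %in% names(results)))
  out <- results[order(results$gene_id), cols]
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e) {
    stop("cannot write results to ", path, ": ", conditionMessage(e))
  })
  on.exit(close(con))
  write.table(format(out, digits = 17, scientific = FALSE, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results TSV written by [write_results()]
#' @param path file path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  tab <- read.delim(path, colClasses = c("character", "integer", "numeric",
                                         "numeric", "logical"))
  tab
}

#' Inner-join genotypes, phenotypes and covariates on sample id
#'
#' Samples present in the genotypes but missing from the phenotype table (or
#' with a missing trait value), and vice versa, are dropped with a
#' `message()` naming the count.
#'
#' @param dataset a [genotype_dataset()].
#' @param phenotypes data.frame from [read_phenotypes()] (or compatible).
#' @param trait trait column name; default = first trait column.
#' @param covariates optional data.frame with `sample_id` plus numeric
#'   covariate columns, joined the same way.
#' @return list with `dataset` (rows aligned), `y` (numeric), `Xf` (fixed
#'   effects: intercept plus covariates), `sample_ids`, `n_dropped`.
#' @export
align_samples <- function(dataset, phenotypes, trait = NULL, covariates = NULL) {
  if (is.null(trait)) trait <- setdiff(names(phenotypes), "sample_id")[1]
  ph <- phenotypes[!is.na(phenotypes[[trait]]), c("sample_id", trait)]
  ids <- intersect(dataset$sample_ids, ph$sample_id)
  if (!is.null(covariates)) {
    cov_ok <- covariates$sample_id[complete.cases(covariates)]
    ids <- intersect(ids, cov_ok)
  }
  n_dropped <- (length(dataset$sample_ids) - length(ids)) +
    (nrow(phenotypes) - length(ids))
  if (length(ids) < 2L) stop("fewer than 2 samples shared between genotypes and phenotypes")
  if (n_dropped > 0L) message("dropped ", n_dropped, " unmatched/incomplete sample record(s)")
  y <- ph[[trait]][match(ids, ph$sample_id)]
  if (length(unique(y[is.finite(y)])) < 2L) {
    stop("trait '", trait, "' has fewer than 2 distinct finite values")
  }
  Xf <- matrix(1, length(ids), 1, dimnames = list(ids, "intercept"))
  if (!is.null(covariates)) {
    cv <- covariates[match(ids, covariates$sample_id),
                     setdiff(names(covariates), "sample_id"), drop = FALSE]
    Xf <- cbind(Xf, as.matrix(cv))
  }
  list(dataset = subset_samples(dataset, ids), y = y, Xf = Xf,
       sample_ids = ids, n_dropped = n_dropped)
}
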