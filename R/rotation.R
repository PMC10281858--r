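# Circular permutation of SNPs over fixed genomic coordinates.  SNP columns
# are rotated around the concatenated genome (after the last SNP of the last
# chromosome one restarts at the first), while slot coordinates — and hence
# the gene membership of each slot — stay fixed.  This reassigns SNPs to
# genes while preserving both LD (relative SNP order is unchanged) and
# population structure / relatedness (sample rows are never touched).

#' Slots participating in the circular rotation
#'
#' Exactly the slots mapped to at least one gene, in genomic order (i.e. the
#' dataset column order restricted to mapped slots).  Unmapped SNPs never
#' enter any neighborhood and are excluded from the rotation domain.
#'
#' @param slot_map a [map_snps_to_genes()] result.
#' @return sorted integer vector of slot indices.
#' @export
participating_slots <- function(slot_map) {
  slots <- which(lengths(slot_map$slot_to_genes) > 0L)
  if (!length(slots)) stop("no SNP maps to any gene; nothing to rotate")
  slots
}

#' Draw distinct rotation offsets
#'
#' Uniform without replacement from \{1, ..., p_total - 1\}; offsets 0 and
#' p_total are excluded because the identity rotation would reproduce the
#' observed statistics.
#'
#' @param np number of rotations wanted.
#' @param p_total number of participating slots.
#' @return integer vector of `np` distinct offsets.
#' @export
sample_rotations <- function(np, p_total) {
  if (np > p_total - 1L) {
    stop(sprintf(
      "np = %d exceeds the %d distinct non-identity rotations available; choose a smaller np",
      np, p_total - 1L))
  }
  sample(seq_len(p_total - 1L), np)
}

#' Slot-to-column assignment for one circular rotation
#'
#' The slot at ordinal i (within the participating slots) receives the
#' genotype column that originally occupied ordinal `(i - r) mod p_total`.
#' Non-participating columns keep their identity assignment (they belong to
#' no gene, so they are never read through the assignment).
#'
#' @param slots participating slot indices from [participating_slots()].
#' @param r rotation offset, `1 <= r <= length(slots) - 1`.
#' @param p total number of genotype columns.
#' @return integer vector `a` of length `p`: the design for a slot s uses
#'   genotype column `a[s]`.
#' @export
rotate_assignment <- function(slots, r, p) {
  pt <- length(slots)
  if (r < 1L || r > pt - 1L) {
    stop(sprintf("rotation offset %d invalid: the identity is forbidden; need 1 <= r <= %d",
                 r, pt - 1L))
  }
  assignment <- seq_len(p)
  assignment[slots] <- slots[((seq_len(pt) - 1L - r) %% pt) + 1L]
  assignment
}
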