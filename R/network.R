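# Gene network and neighborhood machinery: the SNP sets tested by the mixed
# model are the k-hop network neighborhoods of each gene, and the null model
# randomizes the network by degree-preserving double-edge swaps.

#' Construct a gene network
#'
#' An undirected simple graph over gene ids.  Self-loops are removed and
#' duplicate/reversed edges collapsed.
#'
#' @param edges 2-column character matrix (or data.frame) of gene-id pairs.
#' @param nodes optional additional isolated nodes to include.
#' @return object of class `gene_network` with elements `nodes` (character),
#'   `edges` (canonical 2-column matrix) and `graph` (igraph).
#' @export
gene_network <- function(edges, nodes = NULL) {
  edges <- canonical_edges(as.matrix(edges))
  nodes <- sort(unique(c(as.vector(edges), as.character(nodes))))
  if (!length(nodes)) stop("network has no nodes")
  graph <- igraph::make_empty_graph(length(nodes), directed = FALSE)
  graph <- igraph::set_vertex_attr(graph, "name", value = nodes)
  if (nrow(edges)) {
    graph <- igraph::add_edges(graph, t(matrix(match(edges, nodes), ncol = 2)))
  }
  structure(list(nodes = nodes, edges = edges, graph = graph),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %d interactions\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Map SNP slots to genes by genomic position
#'
#' A "slot" is a genotype column ordinal, i.e. a fixed genomic coordinate.
#' Slot s belongs to gene g iff the chromosome matches and
#' `start <= pos <= end` (1-based inclusive on both ends).  A slot may belong
#' to zero, one or several (overlapping) genes.
#'
#' @param dataset a [genotype_dataset()].
#' @param annotation annotation data.frame (see [read_annotation()]).
#' @return object of class `snp_slot_map` with `gene_to_slots` (named list of
#'   sorted slot indices), `slot_to_genes` (list, length p), `p`, and
#'   attribute `empty_genes` (genes with zero slots).
#' @export
map_snps_to_genes <- function(dataset, annotation) {
  annotation <- validate_annotation(annotation)
  p <- length(dataset$snp_ids)
  gene_to_slots <- vector("list", nrow(annotation))
  names(gene_to_slots) <- annotation$gene_id
  slot_to_genes <- rep(list(character()), p)
  for (i in seq_len(nrow(annotation))) {
    slots <- which(dataset$chrom == annotation$chrom[i] &
                   dataset$pos >= annotation$start[i] &
                   dataset$pos <= annotation$end[i])
    gene_to_slots[[i]] <- slots
    for (s in slots) {
      slot_to_genes[[s]] <- c(slot_to_genes[[s]], annotation$gene_id[i])
    }
  }
  empty <- names(gene_to_slots)[lengths(gene_to_slots) == 0L]
  if (length(empty) == nrow(annotation)) {
    warning("no SNP maps to any gene")
  }
  structure(list(gene_to_slots = gene_to_slots,
                 slot_to_genes = slot_to_genes, p = p),
            class = "snp_slot_map", empty_genes = empty)
}

#' Aggregate a gene's k-hop neighborhood into a SNP slot set
#'
#' The neighborhood SNP set of gene v is the union of the SNP slots of v and
#' of every gene at graph distance at most k from v.  A slot shared by two
#' member genes enters once (set union); slots are returned in ascending
#' genomic order.  With `k = 0` this degenerates to the gene's own slots.
#'
#' @param gene gene id; must be a network node.
#' @param network a [gene_network()].
#' @param slot_map a [map_snps_to_genes()] result.
#' @param k hop count (non-negative integer).
#' @return object of class `neighborhood_features`: list with `gene_id`,
#'   `member_genes` (sorted, includes `gene`), `snp_slots` (sorted integer),
#'   `ns` (slot count).
#' @export
aggregate_neighborhood <- function(gene, network, slot_map, k = 1L) {
  if (!(gene %in% network$nodes)) stop("gene not in network: ", gene)
  stopifnot(k >= 0L)
  if (k == 0L) {
    members <- gene
  } else {
    members <- sort(names(igraph::ego(network$graph, order = k,
                                      nodes = gene)[[1]]))
  }
  slots <- sort(unique(unlist(slot_map$gene_to_slots[
    intersect(members, names(slot_map$gene_to_slots))], use.names = FALSE)))
  structure(list(gene_id = gene, member_genes = members,
                 snp_slots = as.integer(slots), ns = length(slots)),
            class = "neighborhood_features")
}

#' Degree-preserving network permutation by double-edge swaps
#'
#' Repeats the swap move — draw two currently connected pairs (va,vb) and
#' (vc,vd); reject the draw if any of va,vb is already connected to any of
#' vc,vd (which also forbids self-loops and parallel edges); otherwise
#' replace the two edges by (va,vc) and (vb,vd) — until at least `fraction`
#' of the original edges are no longer present in the current edge set, or
#' until `max_attempts` candidate draws have been made (then the best-effort
#' graph is returned with a warning).  The degree of every node and the total
#' edge count are preserved exactly.  An original edge re-created by a later
#' swap no longer counts as rearranged.
#'
#' @param network a [gene_network()].
#' @param fraction target fraction of original edges to rearrange, in (0, 1].
#' @param max_attempts candidate-draw cap; default `100 * |E|`.
#' @return a new `gene_network` with the same nodes and degree sequence.
#'   Attribute `rearranged_fraction` records the achieved fraction.
#' @export
permute_network <- function(network, fraction = 0.5, max_attempts = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  ne <- nrow(network$edges)
  if (ne < 2L) stop("need at least 2 edges to permute")
  if (is.null(max_attempts)) max_attempts <- 100L * ne
  nodes <- network$nodes
  idx <- matrix(match(network$edges, nodes), ncol = 2)
  ng <- length(nodes)
  key <- function(a, b) (pmin(a, b) - 1) * ng + pmax(a, b)
  present <- new.env(hash = TRUE, size = 2L * ne)
  for (i in seq_len(ne)) assign(as.character(key(idx[i, 1], idx[i, 2])), TRUE,
                                envir = present)
  orig <- new.env(hash = TRUE, size = 2L * ne)
  for (k0 in as.character(key(idx[, 1], idx[, 2]))) assign(k0, TRUE, envir = orig)
  in_orig <- function(k0) !is.null(orig[[k0]])
  target <- ceiling(fraction * ne)
  rearranged <- 0L
  attempts <- 0L
  edge_has <- function(a, b) !is.null(present[[as.character(key(a, b))]])
  while (rearranged < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    pick <- sample.int(ne, 2L)
    e1 <- idx[pick[1], ]
    e2 <- idx[pick[2], ]
    va <- e1[1]; vb <- e1[2]; vc <- e2[1]; vd <- e2[2]
    # step-2 rejection: any adjacency between {va,vb} and {vc,vd}
    if (va == vc || va == vd || vb == vc || vb == vd) next
    if (edge_has(va, vc) || edge_has(va, vd) ||
        edge_has(vb, vc) || edge_has(vb, vd)) next
    old1 <- as.character(key(va, vb)); old2 <- as.character(key(vc, vd))
    new1 <- as.character(key(va, vc)); new2 <- as.character(key(vb, vd))
    rm(list = c(old1, old2), envir = present)
    assign(new1, TRUE, envir = present)
    assign(new2, TRUE, envir = present)
    idx[pick[1], ] <- c(va, vc)
    idx[pick[2], ] <- c(vb, vd)
    delta <- sum(in_orig(old1), in_orig(old2)) -
      sum(in_orig(new1), in_orig(new2))
    rearranged <- rearranged + delta
  }
  if (rearranged < target) {
    warning(sprintf(
      "edge rearrangement target not reached (%d/%d after %d attempts); returning best effort",
      rearranged, target, attempts))
  }
  out <- gene_network(cbind(nodes[idx[, 1]], nodes[idx[, 2]]), nodes = nodes)
  attr(out, "rearranged_fraction") <- rearranged / ne
  out
}
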