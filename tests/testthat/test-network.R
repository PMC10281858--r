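test_that("SNP-to-gene mapping uses 1-based inclusive intervals", {
  ds <- genotype_dataset(matrix(rep(0:1, 4), 2, 4), paste0("s", 1:4),
                         chrom = rep("1", 4),
                         pos = c(99L, 100L, 150L, 201L),
                         sample_ids = c("a", "b"))
  ann <- data.frame(gene_id = "g1", chrom = "1", start = 100L, end = 200L)
  sm <- map_snps_to_genes(ds, ann)
  expect_identical(sm$gene_to_slots$g1, c(2L, 3L))   # 99 and 201 excluded
  expect_identical(sm$slot_to_genes[[1]], character())
  expect_identical(sm$slot_to_genes[[3]], "g1")
})

test_that("a SNP inside two overlapping genes maps to both", {
  ds <- genotype_dataset(matrix(rep(0:1, 3), 2, 3), paste0("s", 1:3),
                         chrom = rep("1", 3), pos = c(50L, 150L, 260L),
                         sample_ids = c("a", "b"))
  ann <- data.frame(gene_id = c("gA", "gB"), chrom = "1",
                    start = c(100L, 120L), end = c(200L, 300L))
  sm <- map_snps_to_genes(ds, ann)
  expect_setequal(sm$slot_to_genes[[2]], c("gA", "gB"))
  expect_identical(sm$gene_to_slots$gA, 2L)
  expect_identical(sm$gene_to_slots$gB, c(2L, 3L))
  expect_identical(attr(sm, "empty_genes"), character())
})

test_that("k-hop aggregation walks the path graph correctly", {
  ds <- genotype_dataset(matrix(rep(0:1, 6), 2, 6), paste0("s", 1:6),
                         chrom = rep("1", 6), pos = (1:6) * 10L,
                         sample_ids = c("a", "b"))
  ann <- data.frame(gene_id = paste0("g", 1:3), chrom = "1",
                    start = c(10L, 30L, 50L), end = c(20L, 40L, 60L))
  net <- path_network()
  sm <- map_snps_to_genes(ds, ann)

  nb <- aggregate_neighborhood("g2", net, sm, k = 1)
  expect_identical(nb$member_genes, c("g1", "g2", "g3"))
  expect_identical(nb$snp_slots, 1:6)
  expect_identical(nb$ns, 6L)

  nb0 <- aggregate_neighborhood("g2", net, sm, k = 0)
  expect_identical(nb0$member_genes, "g2")
  expect_identical(nb0$snp_slots, 3:4)

  nb2 <- aggregate_neighborhood("g1", net, sm, k = 2)
  expect_identical(nb2$member_genes, c("g1", "g2", "g3"))

  iso <- aggregate_neighborhood("g4", net, sm, k = 1)
  expect_identical(iso$member_genes, "g4")
  expect_identical(iso$ns, 0L)   # g4 has no annotation interval

  expect_error(aggregate_neighborhood("nope", net, sm, 1), "not in network")
})

test_that("aggregation is invariant to edge-list order and orientation", {
  ds <- genotype_dataset(matrix(rep(0:1, 6), 2, 6), paste0("s", 1:6),
                         chrom = rep("1", 6), pos = (1:6) * 10L,
                         sample_ids = c("a", "b"))
  ann <- data.frame(gene_id = paste0("g", 1:3), chrom = "1",
                    start = c(10L, 30L, 50L), end = c(20L, 40L, 60L))
  sm <- map_snps_to_genes(ds, ann)
  n1 <- gene_network(rbind(c("g1", "g2"), c("g2", "g3")))
  n2 <- gene_network(rbind(c("g3", "g2"), c("g2", "g1")))
  a1 <- aggregate_neighborhood("g2", n1, sm, 1)
  a2 <- aggregate_neighborhood("g2", n2, sm, 1)
  expect_identical(a1$snp_slots, a2$snp_slots)
  expect_identical(a1$member_genes, a2$member_genes)
})

test_that("degree-preserving permutation keeps the degree multiset and |E|", {
  set.seed(77)
  g <- igraph::sample_gnm(60, 150)
  igraph::V(g)$name <- paste0("g", 1:60)
  net <- gene_network(igraph::as_edgelist(g))
  deg0 <- sort(igraph::degree(net$graph))
  for (i in 1:20) {
    perm <- permute_network(net, fraction = 0.5)
    expect_identical(sort(igraph::degree(perm$graph)), deg0)
    expect_identical(nrow(perm$edges), nrow(net$edges))
  }
})

test_that("the swap-free complete graph K4 is returned unchanged with a warning", {
  net <- gene_network(t(combn(paste0("g", 1:4), 2)))
  set.seed(1)
  expect_warning(perm <- permute_network(net, fraction = 0.5),
                 "best effort")
  expect_identical(perm$edges, net$edges)
})

test_that("permutation rearranges at least the requested edge fraction", {
  set.seed(99)
  g <- igraph::sample_gnm(100, 250)
  igraph::V(g)$name <- paste0("g", 1:100)
  net <- gene_network(igraph::as_edgelist(g))
  perm <- permute_network(net, fraction = 0.5)
  key <- function(e) paste(e[, 1], e[, 2])
  shared <- length(intersect(key(net$edges), key(perm$edges)))
  expect_lte(shared, 0.5 * nrow(net$edges))
  expect_gte(attr(perm, "rearranged_fraction"), 0.5)
})
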