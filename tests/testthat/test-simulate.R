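test_that("simulated genotypes respect the MAF range", {
  set.seed(81)
  ds <- simulate_genotypes(1000, 60, maf_range = c(0.1, 0.4), block_size = 6)
  maf <- colMeans(ds$dosages) / 2
  expect_true(all(maf > 0.1 - 0.05 & maf < 0.4 + 0.05))
  expect_true(all(ds$dosages %in% 0:2))
})

test_that("block correlation controls adjacent-SNP LD", {
  set.seed(82)
  adj_cor <- function(ds, block_size) {
    p <- ncol(ds$dosages)
    within <- which(seq_len(p - 1) %% block_size != 0 &
                    ds$chrom[-p] == ds$chrom[-1])
    mean(abs(vapply(within, function(j) {
      cor(ds$dosages[, j], ds$dosages[, j + 1])
    }, numeric(1))))
  }
  ds0 <- simulate_genotypes(500, 40, block_size = 8, within_block_corr = 0)
  expect_lt(adj_cor(ds0, 8), 0.15)
  ds9 <- simulate_genotypes(500, 40, block_size = 8, within_block_corr = 0.9)
  expect_gte(adj_cor(ds9, 8), 0.9 * 0.5)
})

test_that("single-SNP blocks give near-independent columns", {
  set.seed(83)
  ds <- simulate_genotypes(800, 20, block_size = 1, within_block_corr = 0.9)
  cc <- cor(ds$dosages)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.15)
})

test_that("the simulated network is simple with the requested edge budget
           and a full gene tiling", {
  set.seed(84)
  ds <- simulate_genotypes(30, 400, block_size = 10)
  sim <- simulate_ppi(80, mean_degree = 4, ds)
  ne <- nrow(sim$network$edges)
  expect_lt(abs(ne - 80 * 4 / 2), 0.1 * 80 * 2)
  expect_identical(anyDuplicated(apply(sim$network$edges, 1, paste,
                                       collapse = "|")), 0L)
  expect_true(all(sim$network$edges[, 1] != sim$network$edges[, 2]))
  sm <- map_snps_to_genes(ds, sim$annotation)
  expect_true(all(lengths(sm$gene_to_slots) >= 1))
  expect_identical(sort(names(sm$gene_to_slots)), sort(sim$network$nodes))
})

test_that("causal configurations realize the requested neighbor ratio", {
  set.seed(85)
  ds <- simulate_genotypes(30, 600, block_size = 10)
  sim <- simulate_ppi(300, mean_degree = 4, ds)
  sm <- map_snps_to_genes(ds, sim$annotation)

  tr <- select_causal_configuration(sim$network, sm,
                                    scenario_config(ncg = 50, rcn = 0.8,
                                                    ng = 300, p = 600))
  expect_identical(length(tr$causal_genes), 50L)
  expect_gte(tr$realized_rcn, 0.7)
  expect_lte(tr$realized_rcn, 0.9)
  expect_true(all(tr$causal_slots %in%
                    unlist(sm$gene_to_slots[tr$causal_genes])))

  tr0 <- select_causal_configuration(sim$network, sm,
                                     scenario_config(ncg = 20, rcn = 0,
                                                     ng = 300, p = 600))
  adjacent <- apply(sim$network$edges, 1, function(e) {
    all(e %in% tr0$causal_genes)
  })
  expect_false(any(adjacent))
  expect_identical(tr0$realized_rcn, 0)

  tr1 <- select_causal_configuration(sim$network, sm,
                                     scenario_config(ncg = 1, rcn = 0.5,
                                                     ng = 300, p = 600))
  expect_identical(length(tr1$causal_genes), 1L)
  expect_identical(tr1$realized_rcn, 0)
})

test_that("phenotypes realize the requested signal mix and noise level", {
  set.seed(86)
  sc <- scenario_config(n = 1000, p = 300, ng = 30, ncg = 5, rcn = 0.4,
                        snr = 2, rln = 1)
  ds <- simulate_genotypes(sc$n, sc$p, block_size = 10)
  sim <- simulate_ppi(sc$ng, 4, ds)
  sm <- map_snps_to_genes(ds, sim$annotation)
  tr <- select_causal_configuration(sim$network, sm, sc)

  ph1 <- simulate_phenotype(ds, tr, sc)
  expect_identical(nrow(attr(ph1, "beta2")), 0L)       # purely linear
  expect_lt(abs(attr(ph1, "realized_snr") - 2) / 2, 0.1)

  sc0 <- sc; sc0$rln <- 0
  ph0 <- simulate_phenotype(ds, tr, sc0)
  expect_gt(nrow(attr(ph0, "beta2")), 0L)
  lin <- drop(scale(ds$dosages[, tr$causal_slots]) %*% attr(ph0, "beta"))
  expect_lt(abs(cor(ph0$sim_trait, lin)), 0.15)        # no linear signal leaks

  expect_error(simulate_phenotype(ds, list(causal_slots = integer()), sc),
               "no causal slots")
})

test_that("AUPRC matches hand-computed precision-recall areas", {
  sc <- c(a = 0.9, b = 0.8, c = 0.3, d = 0.2, e = 0.1)
  expect_equal(as.numeric(evaluate_auprc(sc, c("a", "b"))), 1)
  expect_equal(as.numeric(evaluate_auprc(sc, c("a", "d"))),
               0.5 * 1 + 0.5 * (2 / 4))                # ranks 1 and 4 by hand
  const <- setNames(rep(0.5, 10), letters[1:10])
  expect_equal(as.numeric(evaluate_auprc(const, c("a", "b", "c"))), 0.3)
  expect_equal(attr(evaluate_auprc(const, c("a", "b", "c")), "prevalence"),
               0.3)
  expect_error(evaluate_auprc(sc, "zz"), "undefined")
})

test_that("the scenario grid returns one row per cell and sane AUPRCs", {
  set.seed(88)
  base <- scenario_config(n = 50, p = 60, ng = 8, ncg = 2, rcn = 0,
                          block_size = 5)
  tab <- run_scenario_grid(base, sweep = list(snr = c(0.25, 4)),
                           replicates = 2, methods = "neighborhood",
                           np = 3)
  expect_identical(nrow(tab), 4L)
  expect_true(all(tab$auprc >= 0 & tab$auprc <= 1))
  expect_identical(unique(tab$parameter), "snr")
  expect_identical(unique(tab$prevalence), 2 / 8)
})
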