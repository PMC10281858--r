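test_that("empirical p-values follow the pseudocount tail-count formula", {
  pool <- as.numeric(1:99)
  expect_equal(empirical_pvalue(1000, pool), 1 / 100)   # beats all 99 nulls
  expect_equal(empirical_pvalue(0.5, pool), 1)          # below every null
  expect_equal(empirical_pvalue(51, pool), 50 / 100)    # 49 nulls >= t
  expect_equal(empirical_pvalue(50, pool), 51 / 100)    # ties count for the null
  expect_equal(empirical_pvalue(1000, pool, pseudocount = 0), 0)
})

test_that("p-values are bounded and monotone in the statistic", {
  set.seed(61)
  pool <- rexp(200)
  t <- sort(c(0, runif(50, 0, 5), 10))
  p <- empirical_pvalue(t, pool)
  expect_true(all(p >= 1 / 201) && all(p <= 1))
  expect_true(all(diff(p) <= 0))        # larger t, smaller or equal p
})

test_that("Benjamini-Hochberg matches the hand-derived step-up decisions", {
  # sorted p: 0.01 <= 1/3*.05? yes; 0.02 <= 2/3*.05 = 0.0333? yes; 0.9 no
  res <- bh_procedure(c(0.01, 0.02, 0.9), alpha = 0.05)
  expect_identical(res$rejected, c(TRUE, TRUE, FALSE))
  expect_equal(res$adjusted, c(0.03, 0.03, 0.9))
  expect_identical(bh_procedure(rep(1, 5), 0.05)$rejected, rep(FALSE, 5))
  expect_identical(bh_procedure(0.04, 0.05)$rejected, TRUE)
})

test_that("hierarchical FDR reduces to plain BH for a single trait", {
  set.seed(62)
  p <- runif(30)^2
  h <- hierarchical_fdr(matrix(p, nrow = 1), alpha = 0.05)
  expect_identical(drop(h$significant), bh_procedure(p, 0.05)$rejected)
  expect_identical(sum(hierarchical_fdr(matrix(1, 2, 10), 0.05)$significant), 0L)
})

test_that("hierarchical FDR predominantly selects only the signal trait", {
  set.seed(63)
  only_signal <- 0
  reps <- 50
  for (i in seq_len(reps)) {
    noise <- runif(50)
    signal <- c(10^-runif(10, 4, 6), runif(40))
    h <- hierarchical_fdr(rbind(noise = noise, signal = signal), 0.05)
    # all discoveries confined to the signal trait, most true genes found
    if (sum(h$significant[1, ]) == 0 &&
        sum(h$significant[2, 1:10]) >= 8) {
      only_signal <- only_signal + 1
    }
  }
  expect_gte(only_signal / reps, 0.85)
})

test_that("the null pool has ng' x np statistics, a manifest, and is
           seed-reproducible", {
  study <- small_study()
  y <- study$phenotypes$sim_trait
  Xf <- matrix(1, length(y), 1)
  testable <- sum(vapply(study$network$nodes, function(g) {
    aggregate_neighborhood(g, study$network, study$slot_map, 1)$ns > 0
  }, logical(1)))
  set.seed(64)
  pool1 <- build_null_pool(study$dataset, study$network, study$slot_map, y,
                           Xf, np = 4)
  expect_identical(length(pool1$stats), testable * 4L)
  expect_identical(nrow(pool1$manifest), 4L)
  expect_true(all(pool1$stats >= 0))
  expect_identical(anyDuplicated(pool1$manifest$rotation), 0L)
  set.seed(64)
  pool2 <- build_null_pool(study$dataset, study$network, study$slot_map, y,
                           Xf, np = 4)
  expect_identical(pool1$stats, pool2$stats)
  expect_identical(pool1$manifest, pool2$manifest)
})

test_that("single permutations can be regenerated from the manifest", {
  study <- small_study()
  y <- study$phenotypes$sim_trait
  Xf <- matrix(1, length(y), 1)
  set.seed(65)
  pool <- build_null_pool(study$dataset, study$network, study$slot_map, y,
                          Xf, np = 3)
  m <- 2L
  slots <- participating_slots(study$slot_map)
  assignment <- rotate_assignment(slots, pool$manifest$rotation[m],
                                  study$slot_map$p)
  set.seed(pool$manifest$network_seed[m])
  net_m <- permute_network(study$network, 0.5)
  redo <- compute_set_statistics(study$dataset, net_m, study$slot_map, y, Xf,
                                 k = 1, assignment = assignment)
  ng1 <- length(pool$stats) / 3L
  expect_equal(unname(redo$lrt_statistic[!is.na(redo$lrt_statistic)]),
               pool$stats[(ng1 + 1):(2 * ng1)], tolerance = 1e-12)
})
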