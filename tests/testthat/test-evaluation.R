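test_that("the oracle has zero regret and full win rate; always-X matches its share", {
  kb <- planted_fixture(n = 24L, m = 10L, noise = 0.05, seed = 31L, groups = 4L)
  ev <- lodo_evaluate(kb, list(strategy_oracle(), strategy_always("m01")), seed = 1)
  s <- ev$strategies
  expect_equal(s$mean_regret[s$strategy == "Oracle"], 0)
  expect_equal(s$win_rate[s$strategy == "Oracle"], 1)
  share <- mean(vapply(kb$instances, `[[`, "", "oracle_method") == "m01")
  expect_equal(s$win_rate[s$strategy == "Always-m01"], share)
  # Regret is non-negative for every strategy and instance.
  expect_true(all(ev$per_instance$regret >= -1e-12))
})

test_that("the analytic random strategy reports exact expected values", {
  kb <- planted_fixture(n = 21L, m = 21L, noise = 0.02, seed = 17L, groups = 3L)
  # Continuous perf draws: winners unique, so expected win rate is 1/21.
  ev <- lodo_evaluate(kb, list(strategy_random()), seed = 1)
  expect_equal(ev$strategies$win_rate, 1 / 21, tolerance = 1e-12)
  perf <- misselect:::kb_perf_matrix(kb)
  expect_equal(ev$strategies$mean_auroc, mean(rowMeans(perf)), tolerance = 1e-12)
})

test_that("no fold ever trains on the held-out base group", {
  kb <- planted_fixture(n = 20L, seed = 23L, groups = 5L)
  seen <- list()
  probe <- strategy("Probe", function(train_kb, fingerprint, weights) {
    seen[[length(seen) + 1L]] <<- unique(misselect:::kb_groups(train_kb))
    train_kb$instances[[1]]$oracle_method
  }, "static_knn")
  ev <- lodo_evaluate(kb, list(probe), seed = 1)
  groups_per_instance <- split(ev$per_instance$base_group, ev$per_instance$instance_id)
  # Every test instance's own group was absent from its training store.
  k <- 0L
  for (g in unique(misselect:::kb_groups(kb))) {
    n_test <- sum(misselect:::kb_groups(kb) == g)
    for (i in seq_len(n_test)) {
      k <- k + 1L
      expect_false(g %in% seen[[k]])
    }
  }
})

test_that("dynamic strategies re-learn weights on each fold", {
  kb <- planted_fixture(n = 16L, seed = 29L, groups = 4L)
  ev <- lodo_evaluate(kb, list(strategy_dynamic_knn(k = 3L, config = de_config(maxiter = 15L))),
                      seed = 2)
  expect_length(ev$fold_weights, 4)
  for (w in ev$fold_weights) expect_equal(sum(w), 1, tolerance = 1e-9)
})

test_that("VBS/SBS follows its arithmetic", {
  i1 <- mk_instance("v1", "g1", runif(10), c(A = 0.9, B = 0.5))
  i2 <- mk_instance("v2", "g2", runif(10), c(A = 0.5, B = 0.9))
  g <- vbs_sbs_gap(mk_kb(list(i1, i2)))
  expect_equal(g$vbs, 0.9)
  expect_equal(g$sbs, 0.7)
  expect_equal(g$gap, 0.2)

  # A dominant method closes the gap.
  j1 <- mk_instance("w1", "g1", runif(10), c(A = 0.9, B = 0.5))
  j2 <- mk_instance("w2", "g2", runif(10), c(A = 0.8, B = 0.6))
  expect_equal(vbs_sbs_gap(mk_kb(list(j1, j2)))$gap, 0)
})

test_that("oracle-gap decomposition obeys its accounting identities", {
  # Zero split variance: noise regret identically 0.
  mk_flat <- function(id, g, perf) {
    splits <- matrix(perf, length(perf), 4,
                     dimnames = list(names(perf), NULL))
    mk_instance(id, g, runif(10), perf, splits = splits)
  }
  kb0 <- mk_kb(list(mk_flat("f1", "g1", c(A = 0.8, B = 0.6)),
                    mk_flat("f2", "g2", c(A = 0.6, B = 0.75))))
  recs <- c(f1 = "B", f2 = "A")
  d0 <- decompose_oracle_gap(kb0, recs)
  expect_equal(d0$noise_regret, 0)
  expect_equal(d0$selection_regret, d0$total_gap)

  # Oracle recommendations: zero selection regret.
  kb <- planted_fixture(n = 10L, noise = 0.05, seed = 37L, n_splits = 6L)
  oracle_recs <- setNames(vapply(kb$instances, `[[`, "", "oracle_method"),
                          vapply(kb$instances, `[[`, "", "instance_id"))
  d1 <- decompose_oracle_gap(kb, oracle_recs)
  expect_equal(d1$total_gap, 0)
  expect_equal(d1$selection_regret, 0)
  expect_equal(d1$noise_regret, 0)

  # Components always sum exactly to the total gap.
  other_recs <- setNames(rep(kb$method_ids[1], length(kb$instances)),
                         names(oracle_recs))
  d2 <- decompose_oracle_gap(kb, other_recs)
  expect_equal(d2$noise_regret + d2$selection_regret, d2$total_gap,
               tolerance = 1e-9)
  expect_gte(d2$noise_regret, 0)
  expect_gte(d2$selection_regret, 0)

  kb_nosplit <- planted_fixture(n = 5L, seed = 3L)
  expect_error(decompose_oracle_gap(kb_nosplit, other_recs[1:5]), "data-completeness")
})

test_that("Friedman complementarity matches closed forms and a brute-force rank computation", {
  # Identical rows: every block fully tied, statistic 0.
  flat <- matrix(0.7, 4, 6)
  r <- friedman_complementarity(flat)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)

  # A constant strict ranking of k methods over n blocks: chi2 = n (k - 1).
  k <- 5L; n <- 8L
  perf <- outer(seq_len(k) / 10, rep(1, n)) + matrix(0, k, n)
  r2 <- friedman_complementarity(perf)
  expect_equal(r2$chi2, n * (k - 1))

  # Brute-force re-derivation from average ranks on a random matrix.
  perf3 <- withr::with_seed(6, matrix(runif(5 * 7, 0.5, 0.9), 5, 7))
  ranks <- apply(perf3, 2L, rank)           # rank methods within each block
  rs <- rowSums(ranks)
  chi2_bf <- 12 / (7 * 5 * 6) * sum((rs - 7 * 3)^2)
  r3 <- friedman_complementarity(perf3)
  expect_equal(r3$chi2, chi2_bf, tolerance = 1e-12)
  expect_equal(r3$p, stats::pchisq(chi2_bf, 4, lower.tail = FALSE), tolerance = 1e-12)

  expect_error(friedman_complementarity(matrix(1, 2, 4)), ">= 3 methods")
  bad <- flat; bad[1, 1] <- NA
  expect_error(friedman_complementarity(bad), "completeness")
})

test_that("block bootstrap honours B, the seed and the self-comparison identity", {
  kb <- planted_fixture(n = 20L, noise = 0.05, seed = 41L, groups = 5L)
  ev <- lodo_evaluate(kb, list(strategy_oracle(), strategy_always("m01"),
                               strategy_static_knn(3L)), seed = 1)
  self <- block_bootstrap_delta(ev, "Static-kNN", "Static-kNN", B = 200, seed = 3)
  expect_equal(self$delta, 0)
  expect_equal(unname(self$ci), c(0, 0))

  bb <- block_bootstrap_delta(ev, "Static-kNN", "Always-m01", B = 2000, seed = 4)
  expect_identical(bb$B, 2000L)
  bb2 <- block_bootstrap_delta(ev, "Static-kNN", "Always-m01", B = 2000, seed = 4)
  expect_identical(bb$ci, bb2$ci)
})

test_that("per-condition regrets aggregate exactly to the overall regret", {
  kb <- planted_fixture(n = 18L, noise = 0.05, seed = 47L, groups = 3L)
  # Give instances alternating condition tags.
  for (i in seq_along(kb$instances))
    kb$instances[[i]]$condition <- c("easy", "hard")[1 + i %% 2]
  ev <- lodo_evaluate(kb, list(strategy_always("m02")), seed = 1)
  pc <- ev$per_condition
  counts <- table(ev$per_instance$condition)
  overall <- sum(pc$mean_regret * as.vector(counts[pc$condition])) / sum(counts)
  expect_equal(overall, ev$strategies$mean_regret, tolerance = 1e-12)
})
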