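test_that("the reference portfolio has >= 6 uniquely named methods", {
  port <- reference_portfolio()
  ids <- vapply(port, function(m) m$method_id, "")
  expect_gte(length(ids), 6)
  expect_identical(anyDuplicated(ids), 0L)
})

test_that("indicator-augmented and plain logistic agree on complete data", {
  d <- gen_complete_dataset(150, 4, signal = 1, seed = 2)
  port <- reference_portfolio()
  ids <- vapply(port, function(m) m$method_id, "")
  tr <- 1:100; te <- 101:150
  s1 <- port[[which(ids == "mean_lr")]]$fit_predict(
    d$values[tr, ], d$labels[tr], d$values[te, ], seed = 1)
  s2 <- port[[which(ids == "indicator_lr")]]$fit_predict(
    d$values[tr, ], d$labels[tr], d$values[te, ], seed = 1)
  expect_equal(s1, s2)
})

test_that("evaluation recovers a perfect separator and a permuted null", {
  x <- matrix(rnorm(200 * 3), 200, 3)
  y <- as.integer(x[, 1] > 0)
  sep <- clinical_matrix(x, y, "sep")
  port <- reference_portfolio()
  mean_lr <- port[[which(vapply(port, function(m) m$method_id, "") == "mean_lr")]]
  expect_equal(evaluate_method(sep, mean_lr, n_splits = 5, seed = 1)$mean_auroc, 1)

  null <- clinical_matrix(x, withr::with_seed(4, sample(y)), "null")
  a <- evaluate_method(null, mean_lr, n_splits = 20, seed = 1)$mean_auroc
  expect_lt(abs(a - 0.5), 0.1)
})

test_that("splits are reproducible and stratified within one sample", {
  d <- gen_complete_dataset(147, 4, imbalance = 0.4, signal = 1, seed = 5)
  port <- reference_portfolio()
  mean_lr <- port[[which(vapply(port, function(m) m$method_id, "") == "mean_lr")]]
  r1 <- evaluate_method(d, mean_lr, n_splits = 8, seed = 9)
  r2 <- evaluate_method(d, mean_lr, n_splits = 8, seed = 9)
  expect_identical(r1$per_split_auroc, r2$per_split_auroc)

  # Capture the test rows of each split through a probe method.
  seen <- list()
  probe <- misselect:::new_pipeline_method("probe",
    function(train_x, train_labels, test_x, seed) {
      seen[[length(seen) + 1L]] <<- nrow(test_x)
      rep(0.5, nrow(test_x))
    })
  pool1 <- sum(d$labels == 1L)
  probe_cls <- misselect:::new_pipeline_method("probe2",
    function(train_x, train_labels, test_x, seed) {
      n1_train <- sum(train_labels == 1L)
      seen[[length(seen) + 1L]] <<- n1_train
      rep(0.5, nrow(test_x))
    })
  evaluate_method(d, probe_cls, n_splits = 6, seed = 3)
  k1 <- max(1L, round(0.2 * pool1))
  for (n1_train in unlist(seen))
    expect_lte(abs(n1_train - (pool1 - k1)), 1)
})

test_that("per-split AUROC is invariant to monotone score transforms", {
  d <- gen_complete_dataset(120, 3, signal = 1.5, seed = 6)
  base <- misselect:::new_pipeline_method("raw",
    function(train_x, train_labels, test_x, seed) test_x[, 1])
  warped <- misselect:::new_pipeline_method("warped",
    function(train_x, train_labels, test_x, seed) plogis(3 * test_x[, 1] + 2))
  expect_identical(evaluate_method(d, base, n_splits = 5, seed = 2)$per_split_auroc,
                   evaluate_method(d, warped, n_splits = 5, seed = 2)$per_split_auroc)
})

test_that("run_sweep keeps the books: coverage, feasibility, determinism", {
  d <- gen_base_collection(1, c(90, 90), miss_range = c(0.08, 0.1), seed = 3, f = 5)[[1]]
  port <- reference_portfolio()[c(4, 5)]
  grid <- sweep_grid(c(0.02, 0.3), c(0.5, 1), "MCAR")
  sw <- run_sweep(d, grid, port, n_splits = 3, seed = 1)
  expect_length(sw$cells, 4)
  covered <- vapply(sw$cells, function(c) isTRUE(c$covered), TRUE)
  # Cells below the native rate are uncovered, the rest carry both methods.
  uncovered_miss <- vapply(sw$cells[!covered], function(c) c$condition[["miss"]], 0)
  expect_true(all(uncovered_miss < 0.08))
  expect_true(all(vapply(sw$cells[covered], function(c) length(c$results), 0L) == 2L))

  sw2 <- run_sweep(d, grid, port, n_splits = 3, seed = 1)
  expect_identical(sweep_long(sw), sweep_long(sw2))
})

test_that("performance degrades with injected missingness on strong-signal data", {
  port <- reference_portfolio()
  boost <- port[[which(vapply(port, function(m) m$method_id, "") == "mean_boost")]]
  wins <- 0L
  for (s in 1:3) {
    d <- gen_complete_dataset(300, 8, signal = 2, corr = 0.2, seed = 200 + s)
    grid <- sweep_grid(c(0, 0.5), 1, "MCAR")
    sw <- sweep_long(run_sweep(d, grid, list(boost), n_splits = 8, seed = s))
    if (sw$mean_auroc[sw$miss == 0] >= sw$mean_auroc[sw$miss == 0.5]) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("winner maps resolve ties and report entropy in bits", {
  mk <- function(aurocs, briers = NULL) {
    methods <- names(aurocs)
    mk_sweep("d1", c(0.1, 0.3), c(0.5, 1), "MCAR", methods,
             function(mr, lr, mech, m)
               c(aurocs[[m]], if (is.null(briers)) 0.2 else briers[[m]]))
  }
  # One dominant method everywhere: H = 0.
  wm <- winner_map(list(mk(c(a = 0.8, b = 0.6))))
  expect_identical(unique(wm$winners$method_id), "a")
  expect_equal(wm$entropy_bits, 0)

  # Four methods, each winning one of four cells: H = 2 bits.
  sw4 <- mk_sweep("d2", c(0.1, 0.3), c(0.5, 1), "MCAR", letters[1:4],
                  function(mr, lr, mech, m) {
                    cell <- paste(mr, lr)
                    winner <- c("0.1 0.5" = "a", "0.1 1" = "b",
                                "0.3 0.5" = "c", "0.3 1" = "d")[[cell]]
                    c(if (m == winner) 0.9 else 0.6, 0.2)
                  })
  expect_equal(winner_map(list(sw4))$entropy_bits, 2)

  # AUROC tie resolved by the lower Brier score.
  wm3 <- winner_map(list(mk(c(a = 0.7, b = 0.7), briers = c(a = 0.3, b = 0.1))))
  expect_identical(unique(wm3$winners$method_id), "b")

  expect_error(winner_map(list()), "overlap")
})

test_that("degradation EMD matches hand-computed cases and orders steepness", {
  expect_equal(degradation_emd(c(5, 5, 5), c(0, 0.3, 0.6)), 0)
  # All mass on the first of two points vs uniform: EMD 1/2.
  expect_equal(degradation_emd(c(1, 1e-12), c(0, 1)), 0.5, tolerance = 1e-9)

  grid <- seq(0, 0.6, by = 0.1)
  for (s in 1:5) {
    slopes <- withr::with_seed(s, sort(runif(2, 0.1, 1)))
    shallow <- 1 - slopes[1] * grid
    steep <- 1 - slopes[2] * grid
    expect_lt(degradation_emd(shallow, grid), degradation_emd(steep, grid))
  }
  expect_error(degradation_emd(c(1, -1), c(0, 1)), "positive")
  expect_error(degradation_emd(c(1, 2, 3), c(0, 1)), "equal length")
})
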