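# Fixture builders shared across test files.  Everything is generated in
# code; no stored data.

SENT <- unlabeled_sentinel()

# Clinical matrix with a prescribed missingness mask (TRUE = missing).
cm_from_mask <- function(mask, labels = NULL, seed = 1L) {
  n <- nrow(mask); f <- ncol(mask)
  vals <- withr::with_seed(seed, matrix(rnorm(n * f), n, f))
  vals[mask] <- NA_real_
  if (is.null(labels)) labels <- rep(c(0L, 1L), length.out = n)
  clinical_matrix(vals, labels, "fixture")
}

# Hand-built method_result, bypassing model training.
mk_result <- function(method_id, auroc, brier = 0.25, splits = rep(auroc, 3)) {
  structure(list(method_id = method_id, mean_auroc = auroc,
                 sd_auroc = stats::sd(splits), mean_brier = brier,
                 per_split_auroc = splits),
            class = "method_result")
}

# Hand-built sweep_result over a full grid; `perf_fun(miss, label, mech,
# method_id)` returns c(auroc, brier).
mk_sweep <- function(dataset_id, miss_rates, label_rates, mechanisms,
                     method_ids, perf_fun) {
  grid <- sweep_grid(miss_rates, label_rates, mechanisms)
  cells <- list()
  for (mech in mechanisms) for (mr in miss_rates) for (lr in label_rates) {
    key <- sprintf("%s|m%.3f|l%.3f", mech, mr, lr)
    results <- lapply(method_ids, function(m) {
      pb <- perf_fun(mr, lr, mech, m)
      mk_result(m, pb[1], pb[2])
    })
    names(results) <- method_ids
    cells[[key]] <- list(condition = list(miss = mr, label = lr, mechanism = mech),
                         covered = TRUE, results = results)
  }
  structure(list(dataset_id = dataset_id, base_group = dataset_id,
                 grid = grid, cells = cells),
            class = "sweep_result")
}

# Hand-built meta-instance with a 10-dim fingerprint vector.
mk_instance <- function(id, group, fp10, perf, f11 = 0, condition = "fixture",
                        splits = NULL) {
  fp <- c(stats::setNames(fp10, sprintf("f%d", 1:10)), f11 = f11)
  meta_instance(id, group, condition, fp, perf, splits)
}

mk_kb <- function(instances, method_ids = NULL) {
  if (is.null(method_ids))
    method_ids <- sort(unique(unlist(lapply(instances, function(i) names(i$perf_vector)))))
  misselect:::new_knowledge_base(instances, method_ids)
}

# Planted store used by several modules' tests.
planted_fixture <- function(n = 40L, m = 12L, noise = 0, seed = 11L,
                            n_splits = 0L, groups = 5L) {
  w <- c(0.4, 0.3, rep(0.3 / 8, 8))
  spec <- planted_kb_spec(n, m, true_weights = w, perf_noise_sd = noise,
                          n_groups = groups)
  gen_planted_kb(spec, seed = seed, n_splits = n_splits)
}
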