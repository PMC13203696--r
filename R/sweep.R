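#' Evaluate one pipeline method on one dataset
#'
#' Repeated stratified 80/20 train/test splits of the labeled rows,
#' preserving class balance; unlabeled rows are appended to the training
#' portion (semi-supervised methods may exploit them; others ignore them).
#' AUROC and Brier score are computed on the labeled test rows only.
#' Split seeds are derived from the base seed plus the split index, so the
#' same seed reproduces identical per-split results bit for bit.
#'
#' @param data A [clinical_matrix()] with at least 2 labeled rows per class.
#' @param method A `pipeline_method` from [reference_portfolio()] or a
#'   user-supplied one.
#' @param n_splits Number of stratified splits (30 by default).
#' @param seed Integer base seed.
#' @param test_frac Held-out fraction of labeled rows per split.
#' @return A list of class `method_result`: `method_id`, `mean_auroc`,
#'   `sd_auroc`, `mean_brier`, `per_split_auroc`.
#' @export
evaluate_method <- function(data, method, n_splits = 30L, seed = 1L,
                            test_frac = 0.2) {
  if (!inherits(method, "pipeline_method")) stop_param("method must be a pipeline_method")
  check_scalar(n_splits, "n_splits", lo = 1, integerish = TRUE)
  labeled <- which(data$labels != UNLABELED)
  y <- data$labels[labeled]
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stop_param("need at least 2 labeled rows per class")
  unlabeled <- setdiff(seq_along(data$labels), labeled)

  aurocs <- briers <- numeric(n_splits)
  for (s in seq_len(n_splits)) {
    split_seed <- child_seed(seed, s)
    test_idx <- NULL
    for (attempt in seq_len(10L)) {
      test_idx <- with_seed(child_seed(split_seed, attempt), {
        unlist(lapply(split(labeled, y), function(idx) {
          k <- max(1L, round(test_frac * length(idx)))
          sample(idx, min(k, length(idx) - 1L))
        }), use.names = FALSE)
      })
      yt <- data$labels[test_idx]
      if (any(yt == 1L) && any(yt == 0L)) break
      test_idx <- NULL
    }
    if (is.null(test_idx)) stop("degenerate split: a class is absent from every test draw")
    train_idx <- c(setdiff(labeled, test_idx), unlabeled)
    scores <- method$fit_predict(data$values[train_idx, , drop = FALSE],
                                 data$labels[train_idx],
                                 data$values[test_idx, , drop = FALSE],
                                 seed = split_seed)
    yt <- data$labels[test_idx]
    aurocs[s] <- auroc(scores, yt)
    briers[s] <- brier(scores, yt)
  }
  structure(list(method_id = method$method_id,
                 mean_auroc = mean(aurocs),
                 sd_auroc = if (n_splits > 1L) sd(aurocs) else 0,
                 mean_brier = mean(briers),
                 per_split_auroc = aurocs),
            class = "method_result")
}

#' Define a sweep grid
#'
#' @param miss_rates Increasing vector of target global missing rates.
#' @param label_rates Vector of label retention rates in (0, 1].
#' @param mechanisms Subset of `c("MCAR", "MNAR")`.
#' @return A `sweep_grid` object.
#' @export
sweep_grid <- function(miss_rates, label_rates, mechanisms = c("MCAR", "MNAR")) {
  if (any(miss_rates < 0 | miss_rates >= 1)) stop_param("miss_rates must lie in [0, 1)")
  if (any(label_rates <= 0 | label_rates > 1)) stop_param("label_rates must lie in (0, 1]")
  mechanisms <- match.arg(mechanisms, c("MCAR", "MNAR"), several.ok = TRUE)
  structure(list(miss_rates = sort(unique(miss_rates)),
                 label_rates = sort(unique(label_rates)),
                 mechanisms = mechanisms),
            class = "sweep_grid")
}

cell_key <- function(miss, label, mech) sprintf("%s|m%.3f|l%.3f", mech, miss, label)

#' Run a degradation sweep over a pipeline portfolio
#'
#' For every grid cell (missing rate x label rate x mechanism) the
#' condition is applied to a fresh copy of the dataset and every portfolio
#' method is evaluated.  Cells whose missing-rate target falls below the
#' dataset's native rate (or whose label target exceeds the labeled
#' fraction) are marked uncovered rather than failing; per-cell errors are
#' likewise recorded without aborting the sweep.
#'
#' @param data A [clinical_matrix()].
#' @param grid A [sweep_grid()].
#' @param portfolio List of `pipeline_method`s.
#' @param n_splits Stratified splits per evaluation.
#' @param seed Integer base seed.
#' @return A list of class `sweep_result`: `dataset_id`, `base_group`,
#'   `grid`, and `cells` (a named list with `condition`, `covered`, and
#'   the per-method `results`).
#' @export
run_sweep <- function(data, grid, portfolio, n_splits = 30L, seed = 1L) {
  if (!inherits(grid, "sweep_grid")) stop_param("grid must be a sweep_grid")
  ids <- vapply(portfolio, function(m) m$method_id, "")
  if (anyDuplicated(ids)) stop_param("portfolio method_ids must be unique")
  native <- global_missing_rate(data)
  lab_frac <- labeled_fraction(data)
  cells <- list()
  ci <- 0L
  for (mech in grid$mechanisms) for (mr in grid$miss_rates) for (lr in grid$label_rates) {
    ci <- ci + 1L
    key <- cell_key(mr, lr, mech)
    if (mr < native - 1e-12 || lr > lab_frac + 1e-12) {
      cells[[key]] <- list(condition = list(miss = mr, label = lr, mechanism = mech),
                           covered = FALSE, reason = "infeasible target")
      next
    }
    mech_eff <- if (mr <= native + 1e-12) "natural" else mech
    cond <- degradation_condition(key, mr, lr, mech_eff)
    cell_seed <- child_seed(seed, ci)
    res <- tryCatch({
      degraded <- apply_condition(data, cond, seed = cell_seed)
      lapply(portfolio, function(m)
        evaluate_method(degraded, m, n_splits = n_splits,
                        seed = child_seed(cell_seed, 97L)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      cells[[key]] <- list(condition = list(miss = mr, label = lr, mechanism = mech),
                           covered = FALSE, reason = conditionMessage(res))
    } else {
      names(res) <- ids
      cells[[key]] <- list(condition = list(miss = mr, label = lr, mechanism = mech),
                           covered = TRUE, results = res)
    }
  }
  structure(list(dataset_id = data$dataset_id, base_group = data$base_group,
                 grid = grid, cells = cells),
            class = "sweep_result")
}

#' Long-format view of a sweep result
#'
#' @param sweep A `sweep_result`.
#' @return A data frame with one row per covered cell x method:
#'   `dataset_id`, `miss`, `label`, `mechanism`, `method_id`,
#'   `mean_auroc`, `sd_auroc`, `mean_brier`.
#' @export
sweep_long <- function(sweep) {
  rows <- list()
  for (cell in sweep$cells) {
    if (!isTRUE(cell$covered)) next
    for (r in cell$results)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset_id = sweep$dataset_id,
        miss = cell$condition$miss,
        label = cell$condition$label,
        mechanism = cell$condition$mechanism,
        method_id = r$method_id,
        mean_auroc = r$mean_auroc, sd_auroc = r$sd_auroc,
        mean_brier = r$mean_brier)
  }
  do.call(rbind, rows)
}

#' Cross-dataset winner map and winner entropy
#'
#' For each grid cell covered by at least one sweep, the winning method is
#' the one with the highest cross-dataset mean AUROC; ties break by lower
#' mean Brier, then lexicographic `method_id`.  Winner entropy is the
#' Shannon entropy (bits) of the winner distribution over covered cells.
#'
#' @param sweeps A list of `sweep_result`s with overlapping coverage.
#' @return A list with `winners` (data frame: cell, miss, label,
#'   mechanism, method_id, mean_auroc) and `entropy_bits`.
#' @export
winner_map <- function(sweeps) {
  longs <- do.call(rbind, lapply(sweeps, sweep_long))
  if (is.null(longs) || nrow(longs) == 0L)
    stop_param("no covered cells: sweeps have empty overlap")
  longs$cell <- cell_key(longs$miss, longs$label, longs$mechanism)
  agg <- aggregate(cbind(mean_auroc, mean_brier) ~ cell + method_id + miss + label + mechanism,
                   data = longs, FUN = mean)
  winners <- do.call(rbind, lapply(split(agg, agg$cell), function(df) {
    df <- df[order(-df$mean_auroc, df$mean_brier, df$method_id), ]
    df[1L, c("cell", "miss", "label", "mechanism", "method_id", "mean_auroc")]
  }))
  rownames(winners) <- NULL
  list(winners = winners,
       entropy_bits = entropy_bits(table(winners$method_id)))
}

#' Earth mover's distance of a degradation curve from flat
#'
#' Normalizes a positive AUROC-versus-missing-rate curve to a probability
#' distribution over the grid points and returns its 1-D Wasserstein
#' distance from the uniform distribution on the same points.  A flat
#' curve gives 0; steeper declines concentrate mass and give larger
#' values.
#'
#' @param curve Positive numeric vector of performance values.
#' @param grid Increasing vector of missing rates, same length as `curve`.
#' @return A non-negative scalar.
#' @export
degradation_emd <- function(curve, grid) {
  if (length(curve) != length(grid) || length(curve) < 2L)
    stop_param("curve and grid must have equal length >= 2")
  if (any(curve <= 0)) stop_param("curve must be strictly positive")
  if (is.unsorted(grid, strictly = TRUE)) stop_param("grid must be strictly increasing")
  p <- curve / sum(curve)
  u <- rep(1 / length(p), length(p))
  cdf_gap <- cumsum(p - u)
  sum(abs(cdf_gap[-length(p)]) * diff(grid))
}
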