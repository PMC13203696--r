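#' Named degradation condition
#'
#' Bundles a missingness-injection target, a label-retention rate and a
#' mechanism into a named quality condition.  `miss_target` is the target
#' *global* missing rate after injection (including any pre-existing
#' missingness); `label_rate` is the fraction of currently labeled rows to
#' retain.
#'
#' @param tag Condition name (unique within a grid).
#' @param miss_target Target global missing rate in \[0, 1).
#' @param label_rate Label retention rate in (0, 1].
#' @param mechanism One of `"natural"`, `"MCAR"`, `"MNAR"`.
#' @return A `degradation_condition` object.
#' @export
degradation_condition <- function(tag, miss_target, label_rate, mechanism) {
  if (!is.character(tag) || length(tag) != 1L || !nzchar(tag))
    stop_param("tag must be a non-empty string")
  check_scalar(miss_target, "miss_target", lo = 0)
  if (miss_target >= 1) stop_param("miss_target must be < 1")
  check_scalar(label_rate, "label_rate", lo = 1e-12, hi = 1)
  mechanism <- match.arg(mechanism, c("natural", "MCAR", "MNAR"))
  structure(list(tag = tag, miss_target = miss_target,
                 label_rate = label_rate, mechanism = mechanism),
            class = "degradation_condition")
}

#' The six-condition augmentation grid
#'
#' The default constructive-augmentation grid: six named conditions
#' spanning the quality space from an untouched half-labeled baseline to
#' heavy MCAR (50\% missing, 10\% labels) and heavy MNAR (40\% missing,
#' 10\% labels).
#'
#' @return A list of six [degradation_condition()] objects.
#' @export
augmentation_grid <- function() {
  list(
    degradation_condition("baseline halflabel", 0.00, 0.50, "natural"),
    degradation_condition("light MCAR",         0.10, 0.60, "MCAR"),
    degradation_condition("moderate MCAR",      0.30, 0.20, "MCAR"),
    degradation_condition("heavy MCAR",         0.50, 0.10, "MCAR"),
    degradation_condition("moderate MNAR",      0.20, 0.40, "MNAR"),
    degradation_condition("heavy MNAR",         0.40, 0.10, "MNAR"))
}

#' Inject missing-completely-at-random cells
#'
#' Masks each currently observed cell independently with probability
#' `p = (t - c) / (1 - c)`, where `t` is the target global missing rate
#' and `c` the current one, so the expected post-injection rate is exactly
#' `t`.  Labels are never touched; the missing-cell set only grows.
#'
#' @param data A [clinical_matrix()].
#' @param target_rate Target global missing rate `t` in \[`c`, 1).
#' @param seed Integer seed.
#' @return The degraded [clinical_matrix()] (identical input when
#'   `t == c`).
#' @export
inject_mcar <- function(data, target_rate, seed) {
  if (!inherits(data, "clinical_matrix")) stop_param("data must be a clinical_matrix")
  check_scalar(target_rate, "target_rate", lo = 0)
  if (target_rate >= 1) stop_param("target_rate must be < 1")
  check_scalar(seed, "seed", integerish = TRUE)
  c0 <- global_missing_rate(data)
  if (target_rate < c0 - 1e-12)
    stop_param("infeasible target: current missing rate ", signif(c0, 4),
               " exceeds target ", target_rate)
  p <- (target_rate - c0) / (1 - c0)
  if (p <= 0) return(data)
  obs <- which(!is.na(data$values))
  with_seed(seed, {
    drop <- obs[runif(length(obs)) < p]
    data$values[drop] <- NA_real_
  })
  append_provenance(data, sprintf("inject_mcar(t=%.3f)", target_rate))
}

#' Inject missing-not-at-random cells by noisy rank-threshold masking
#'
#' Per column, observed values receive normalized ranks in \[0, 1\]
#' perturbed by additive Gaussian noise of standard deviation `sigma`;
#' exactly the `ceiling(q * n_obs)` cells with the lowest noisy ranks are
#' masked, where `q = (t - c) / (1 - c)` is the per-column masking rate
#' that reaches the global target `t`.  The bottom-quantile rule mimics
#' clinical left-tail missingness (low values selectively unrecorded);
#' `sigma = 0` gives the exact bottom-`q` quantile.  Exact-count masking
#' makes the realized rate equal `t` up to per-column rounding.
#'
#' The newly masked cells' underlying values are retained in the
#' `masked_values` attribute (a data frame of row, column, value) so the
#' left-tail bias is verifiable.
#'
#' @param data A [clinical_matrix()].
#' @param target_rate Target global missing rate `t` in \[`c`, 1).
#' @param sigma Gaussian rank-noise standard deviation.
#' @param seed Integer seed.
#' @return The degraded [clinical_matrix()].
#' @export
inject_mnar <- function(data, target_rate, sigma = 0.15, seed) {
  if (!inherits(data, "clinical_matrix")) stop_param("data must be a clinical_matrix")
  check_scalar(target_rate, "target_rate", lo = 0)
  if (target_rate >= 1) stop_param("target_rate must be < 1")
  check_scalar(sigma, "sigma", lo = 0)
  check_scalar(seed, "seed", integerish = TRUE)
  c0 <- global_missing_rate(data)
  if (target_rate < c0 - 1e-12)
    stop_param("infeasible target: current missing rate ", signif(c0, 4),
               " exceeds target ", target_rate)
  q <- (target_rate - c0) / (1 - c0)
  if (q <= 0) return(data)

  masked_log <- list()
  with_seed(seed, {
    for (j in seq_len(ncol(data$values))) {
      v <- data$values[, j]
      obs <- which(!is.na(v))
      n_obs <- length(obs)
      if (n_obs < 2L) {
        message("inject_mnar: column ", j, " has < 2 observed values; skipped")
        next
      }
      k <- min(ceiling(q * n_obs), n_obs)
      if (k == 0L) next
      r <- (rank(v[obs], ties.method = "average") - 0.5) / n_obs
      noisy <- r + if (sigma > 0) rnorm(n_obs, 0, sigma) else 0
      drop <- obs[order(noisy)[seq_len(k)]]
      masked_log[[length(masked_log) + 1L]] <-
        data.frame(row = drop, col = j, value = v[drop])
      data$values[drop, j] <- NA_real_
    }
  })
  out <- append_provenance(data, sprintf("inject_mnar(t=%.3f,sigma=%.2f)",
                                         target_rate, sigma))
  attr(out, "masked_values") <- do.call(rbind, masked_log)
  out
}

#' Trim labels by class-stratified subsampling
#'
#' Retains exactly `round(label_rate * N)` labels (so the labeled fraction
#' f2 hits `label_rate`), allocated across classes by largest-remainder
#' rounding of the class proportions so the retained set preserves class
#' balance; all other labeled rows get the unlabeled sentinel.  Feature
#' values and the missing mask are never altered.  For a fully labeled
#' dataset this retains `round(label_rate * N_labeled)` labels.
#'
#' @param data A [clinical_matrix()].
#' @param label_rate Target labeled fraction, in
#'   (0, current labeled fraction\]; equality is the identity.
#' @param seed Integer seed.
#' @return The trimmed [clinical_matrix()].
#' @export
trim_labels <- function(data, label_rate, seed) {
  if (!inherits(data, "clinical_matrix")) stop_param("data must be a clinical_matrix")
  check_scalar(label_rate, "label_rate", lo = 1e-12, hi = 1)
  check_scalar(seed, "seed", integerish = TRUE)
  labeled <- which(data$labels != UNLABELED)
  frac <- length(labeled) / length(data$labels)
  if (label_rate > frac + 1e-12)
    stop_param("infeasible target: label_rate ", label_rate,
               " exceeds current labeled fraction ", signif(frac, 4))
  n_keep <- round(label_rate * length(data$labels))
  if (n_keep >= length(labeled)) return(data)

  by_class <- split(labeled, data$labels[labeled])
  exact <- vapply(by_class, length, 0L) * n_keep / length(labeled)
  base <- floor(exact)
  short <- n_keep - sum(base)
  if (short > 0) {
    order_frac <- order(exact - base, decreasing = TRUE)
    base[order_frac[seq_len(short)]] <- base[order_frac[seq_len(short)]] + 1
  } else if (short < 0) {
    order_frac <- order(exact - base)
    take <- order_frac[seq_len(-short)]
    base[take] <- pmax(base[take] - 1, 0)
  }
  with_seed(seed, {
    keep <- unlist(lapply(seq_along(by_class), function(i) {
      idx <- by_class[[i]]
      if (base[i] >= length(idx)) idx else sample(idx, base[i])
    }), use.names = FALSE)
    drop <- setdiff(labeled, keep)
    data$labels[drop] <- UNLABELED
  })
  append_provenance(data, sprintf("trim_labels(rate=%.3f)", label_rate))
}

#' Apply a named degradation condition
#'
#' Order of operations: missingness injection first (skipped for
#' `mechanism = "natural"` or a zero target), then label trimming.  The
#' condition tag is recorded in the dataset's provenance.
#'
#' @param data A [clinical_matrix()].
#' @param cond A [degradation_condition()].
#' @param seed Integer seed (injection and trimming draw from derived
#'   child seeds).
#' @return The degraded [clinical_matrix()].
#' @export
apply_condition <- function(data, cond, seed) {
  if (!inherits(cond, "degradation_condition"))
    stop_param("cond must be a degradation_condition")
  check_scalar(seed, "seed", integerish = TRUE)
  out <- data
  if (cond$mechanism != "natural" && cond$miss_target > 0) {
    out <- switch(cond$mechanism,
      MCAR = inject_mcar(out, cond$miss_target, seed = child_seed(seed, 1L)),
      MNAR = inject_mnar(out, cond$miss_target, seed = child_seed(seed, 2L)))
  }
  out <- trim_labels(out, cond$label_rate, seed = child_seed(seed, 3L))
  append_provenance(out, sprintf("condition:%s", cond$tag))
}
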