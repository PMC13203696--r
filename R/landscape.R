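#' Method-agnostic landscape descriptors of a sweep surface
#'
#' Ten descriptors of the shape of a dataset's performance surface that
#' never reference a specific method identity (they are invariant to
#' method relabeling):
#'
#' * d1/d2 `baseline_dispersion` / `stress_dispersion`: sd of method mean
#'   AUROCs at the easiest / hardest covered cell, where easiest =
#'   (min miss, max label) and hardest = (max covered miss, min covered
#'   label), averaged over mechanisms present at that cell.
#' * d3/d4 `mean_auroc_slope` / `mean_brier_slope`: mean over methods of
#'   the least-squares slope of AUROC (Brier) against missing rate.
#' * d5 `mnar_mcar_gap`: mean over methods and matched cells of
#'   AUROC(MNAR) - AUROC(MCAR).
#' * d6 `winner_stability`: fraction of covered cells won by the modal
#'   winner; d7 `winner_diversity`: winner entropy in bits (d7 = 0 iff
#'   d6 = 1).
#' * d8 `label_efficiency_spread`: sd over methods of AUROC at the highest
#'   minus the lowest covered label rate.
#' * d9 `pareto_size`: number of methods non-dominated in (mean AUROC up,
#'   mean Brier down).
#' * d10 `calibration_discordance`: 1 - Spearman correlation between
#'   method rankings by mean AUROC and by negative mean Brier (0 when the
#'   rankings agree or are degenerate).
#'
#' @param sweep A `sweep_result` covering at least 2 missing rates and 2
#'   label rates.
#' @return A named numeric vector `d1`...`d10` of class
#'   `landscape_descriptor`.
#' @export
compute_landscape <- function(sweep) {
  long <- sweep_long(sweep)
  if (is.null(long)) stop_param("coverage error: sweep has no covered cells")
  if (length(unique(long$miss)) < 2L || length(unique(long$label)) < 2L)
    stop_param("coverage error: need >= 2 covered missing rates and >= 2 label rates; have ",
               length(unique(long$miss)), " and ", length(unique(long$label)))

  ease <- long[long$miss == min(long$miss) & long$label == max(long$label), ]
  hard <- long[long$miss == max(long$miss) & long$label == min(long$label), ]
  disp <- function(df) {
    if (!nrow(df)) return(NA_real_)
    m <- aggregate(mean_auroc ~ method_id, df, mean)
    if (nrow(m) > 1L) sd(m$mean_auroc) else 0
  }
  d1 <- disp(ease); d2 <- disp(hard)

  slope <- function(value) {
    per_method <- split(long, long$method_id)
    mean(vapply(per_method, function(df) {
      m <- aggregate(df[[value]], list(miss = df$miss), mean)
      if (nrow(m) < 2L) return(0)
      stats::cov(m$miss, m$x) / stats::var(m$miss)
    }, 0))
  }
  d3 <- slope("mean_auroc"); d4 <- slope("mean_brier")

  both <- merge(long[long$mechanism == "MNAR", c("miss", "label", "method_id", "mean_auroc")],
                long[long$mechanism == "MCAR", c("miss", "label", "method_id", "mean_auroc")],
                by = c("miss", "label", "method_id"), suffixes = c("_mnar", "_mcar"))
  d5 <- if (nrow(both)) mean(both$mean_auroc_mnar - both$mean_auroc_mcar) else 0

  long$cell <- cell_key(long$miss, long$label, long$mechanism)
  winners <- vapply(split(long, long$cell), function(df) {
    df <- df[order(-df$mean_auroc, df$mean_brier, df$method_id), ]
    df$method_id[1L]
  }, "")
  tab <- table(winners)
  d6 <- max(tab) / length(winners)
  d7 <- entropy_bits(tab)

  lab_hi <- aggregate(mean_auroc ~ method_id, long[long$label == max(long$label), ], mean)
  lab_lo <- aggregate(mean_auroc ~ method_id, long[long$label == min(long$label), ], mean)
  spread <- merge(lab_hi, lab_lo, by = "method_id", suffixes = c("_hi", "_lo"))
  d8 <- if (nrow(spread) > 1L) sd(spread$mean_auroc_hi - spread$mean_auroc_lo) else 0

  overall <- aggregate(cbind(mean_auroc, mean_brier) ~ method_id, long, mean)
  dominated <- vapply(seq_len(nrow(overall)), function(i) {
    any(overall$mean_auroc >= overall$mean_auroc[i] &
        overall$mean_brier <= overall$mean_brier[i] &
        (overall$mean_auroc > overall$mean_auroc[i] |
         overall$mean_brier < overall$mean_brier[i]))
  }, TRUE)
  d9 <- sum(!dominated)

  rho <- spearman(overall$mean_auroc, -overall$mean_brier)
  d10 <- if (is.na(rho)) 0 else 1 - rho

  structure(c(d1 = d1, d2 = d2, d3 = d3, d4 = d4, d5 = d5,
              d6 = d6, d7 = d7, d8 = d8, d9 = d9, d10 = d10),
            class = "landscape_descriptor")
}

#' Dynamic distance between two meta-instances
#'
#' Euclidean distance between per-method performance vectors, restricted
#' to the methods both instances cover and rescaled by
#' `sqrt(M / m_shared)` (`M` = full method count) so partially-overlapping
#' pairs remain comparable to fully-overlapping ones.  This is the
#' supervision signal for metric learning: it requires sweep data and is
#' unavailable for new datasets at deployment.
#'
#' @param a,b `meta_instance`s sharing at least 2 methods with
#'   performance entries.
#' @return A non-negative scalar; 0 iff the shared subvectors are equal.
#' @export
dynamic_distance <- function(a, b) {
  shared <- intersect(names(a$perf_vector)[!is.na(a$perf_vector)],
                      names(b$perf_vector)[!is.na(b$perf_vector)])
  if (length(shared) < 2L)
    stop_param("incomparable instances: fewer than 2 shared methods")
  m_full <- max(length(a$perf_vector), length(b$perf_vector))
  sqrt(sum((a$perf_vector[shared] - b$perf_vector[shared])^2)) *
    sqrt(m_full / length(shared))
}
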