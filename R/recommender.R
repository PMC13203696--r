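#' Recommend pipelines for a new dataset fingerprint
#'
#' Weighted k-nearest-neighbour frequency vote over the knowledge base:
#' the k stored instances closest to the query under
#' [weighted_static_distance()] (f1-f10 only; f11 never enters) vote with
#' their oracle methods.  Methods are ranked by vote count, then by mean
#' performance across the k neighbours, then lexicographically.  An
#' out-of-distribution report ([ood_flags()]) accompanies every
#' recommendation.
#'
#' @param query A fingerprint (named vector with `f1`...`f10`), e.g. from
#'   [compute_fingerprint()].
#' @param kb A `knowledge_base`.
#' @param w Length-10 weight vector (e.g. `learn_weights(kb)$weights`);
#'   uniform weights give plain kNN.
#' @param k Neighbourhood size (clamped to the store size with a notice).
#' @return A list of class `recommendation`: `ranked_methods` (data frame
#'   with `method_id`, `votes`, `mean_neighbour_auroc`), `neighbours`
#'   (instance ids, distances, oracle methods, non-decreasing distance),
#'   `k`, `weights`, `ood`.
#' @export
recommend <- function(query, kb, w, k = 5L) {
  if (!inherits(kb, "knowledge_base")) stop_param("kb must be a knowledge_base")
  check_scalar(k, "k", lo = 1, integerish = TRUE)
  n <- length(kb$instances)
  if (k > n) {
    message("recommend: k = ", k, " exceeds store size ", n, "; clamped")
    k <- n
  }
  d <- vapply(kb$instances, function(i)
    weighted_static_distance(query, i$fingerprint, w), 0)
  ids <- vapply(kb$instances, `[[`, "", "instance_id")
  ord <- order(d, ids)                      # deterministic under distance ties
  nb <- ord[seq_len(k)]
  nb_oracle <- vapply(kb$instances[nb], `[[`, "", "oracle_method")

  votes <- table(factor(nb_oracle, levels = sort(unique(nb_oracle))))
  perf_nb <- kb_perf_matrix(kb_subset(kb, nb))
  mean_perf <- colMeans(perf_nb, na.rm = TRUE)
  ranked <- data.frame(method_id = names(votes),
                       votes = as.integer(votes),
                       mean_neighbour_auroc = unname(mean_perf[names(votes)]))
  ranked <- ranked[order(-ranked$votes, -ranked$mean_neighbour_auroc,
                         ranked$method_id), ]
  rownames(ranked) <- NULL

  structure(list(ranked_methods = ranked,
                 neighbours = data.frame(instance_id = ids[nb],
                                         distance = d[nb],
                                         oracle_method = nb_oracle),
                 k = k, weights = w,
                 ood = ood_flags(query, kb, w)),
            class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  cat("<recommendation> top:", x$ranked_methods$method_id[1L],
      sprintf("(votes %d/%d)\n", x$ranked_methods$votes[1L], x$k))
  print(utils::head(x$ranked_methods, 3L))
  if (x$ood$distrust)
    cat("  ! OOD distrust flag set (", x$ood$n_ood_dims, "dims out of range )\n")
  invisible(x)
}

#' Out-of-distribution safeguards for a query fingerprint
#'
#' Flags each of the ten structural dimensions whose query value lies
#' outside the stored \[min, max\] envelope.  The recommendation is
#' distrusted when the query is out of range on >= 3 dimensions, or when
#' its nearest-neighbour distance exceeds the 95th percentile of all
#' stored unordered pairwise weighted distances; distrusted queries
#' should be validated with a targeted sweep of the shortlist.
#'
#' @param query Fingerprint (named, `f1`...`f10`).
#' @param kb A `knowledge_base` with >= 2 instances.
#' @param w Length-10 weight vector.
#' @return A list of class `ood_report`: `dim_flags` (named logical),
#'   `n_ood_dims`, `nn_distance`, `nn_distance_p95_store`, `distrust`.
#' @export
ood_flags <- function(query, kb, w) {
  if (length(kb$instances) < 2L) stop_param("kb must hold >= 2 instances")
  dims <- sprintf("f%d", 1:10)
  fp <- kb_fingerprints(kb)
  q <- unclass(query)[dims]
  lo <- apply(fp, 2L, min); hi <- apply(fp, 2L, max)
  flags <- q < lo | q > hi
  d <- vapply(kb$instances, function(i)
    weighted_static_distance(query, i$fingerprint, w), 0)
  p95 <- unname(quantile(wsd_pairs(fp, w), 0.95, type = 7))
  nn <- min(d)
  structure(list(dim_flags = setNames(flags, dims),
                 n_ood_dims = sum(flags),
                 nn_distance = nn,
                 nn_distance_p95_store = p95,
                 distrust = sum(flags) >= 3L || nn > p95),
            class = "ood_report")
}

#' Two-rule mechanism-aware fallback
#'
#' The minimal mechanism-aware baseline usable without any knowledge
#' base: run Little's MCAR test on the dataset; when the test does not
#' reject MCAR (p >= alpha) recommend the MCAR-regime default, otherwise
#' recommend a missingness-aware method.  Datasets that do not admit the
#' test (a single missingness pattern) fall back to the MCAR default with
#' a flag.
#'
#' @param data A [clinical_matrix()].
#' @param mcar_default Method id to use under MCAR (the modal MCAR-regime
#'   winner in the knowledge base).
#' @param nonmcar_default Missingness-aware method id for the rejecting
#'   case.
#' @param alpha Significance level (0 always yields the MCAR default).
#' @return The chosen method id, with attributes `p_value` and `flagged`
#'   (TRUE when the test was not computable).
#' @export
two_rule_recommend <- function(data, mcar_default, nonmcar_default,
                               alpha = 0.05) {
  check_scalar(alpha, "alpha", lo = 0, hi = 1)
  res <- tryCatch(littles_mcar_test(data), error = function(e) NULL)
  if (is.null(res) || res$df <= 0L)
    return(structure(mcar_default, p_value = NA_real_, flagged = TRUE))
  choice <- if (res$p_value >= alpha) mcar_default else nonmcar_default
  structure(choice, p_value = res$p_value, flagged = FALSE)
}
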