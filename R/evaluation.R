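#' Recommendation strategies for the evaluation harness
#'
#' A strategy maps a training knowledge base and a test instance's
#' fingerprint to a method id.  Non-oracle strategies receive only the
#' fingerprint and the training store (they can never see the test
#' instance's performance vector); the oracle is the one sanctioned
#' exception and defines the regret zero-point.
#'
#' * `strategy_random()`: uniform random selection, evaluated
#'   analytically by default (expected AUROC = mean over methods; expected
#'   win = fraction of methods tied for best).
#' * `strategy_always(method_id)`: a fixed default.
#' * `strategy_static_knn(k)`: kNN vote under uniform weights.
#' * `strategy_dynamic_knn(k, config)`: kNN vote under weights re-learned
#'   on each LODO fold via [learn_weights()].
#' * `strategy_two_rule(...)`: Little's-test dichotomy using the stored
#'   f11 (`p = 10^-f11`).
#' * `strategy_oracle()`: per-instance best method.
#'
#' @param name Display name.
#' @param rule Function `(train_kb, fingerprint, weights)` returning a
#'   method id (ignored for the `random` and `oracle` families).
#' @param family One of `"random"`, `"always_X"`, `"static_knn"`,
#'   `"dynamic_learned_knn"`, `"two_rule"`, `"oracle"`.
#' @return A `strategy` object.
#' @export
strategy <- function(name, rule, family) {
  family <- match.arg(family, c("random", "always_X", "static_knn",
                                "dynamic_learned_knn", "two_rule", "oracle"))
  structure(list(name = name, rule = rule, family = family), class = "strategy")
}

#' @rdname strategy
#' @export
strategy_random <- function() strategy("Random", NULL, "random")

#' @rdname strategy
#' @param method_id Fixed method for `strategy_always`.
#' @export
strategy_always <- function(method_id)
  strategy(paste0("Always-", method_id),
           function(train_kb, fingerprint, weights) method_id, "always_X")

#' @rdname strategy
#' @param k Neighbourhood size for the kNN strategies.
#' @export
strategy_static_knn <- function(k = 5L)
  strategy("Static-kNN",
           function(train_kb, fingerprint, weights)
             recommend(fingerprint, train_kb, rep(1, 10), k)$ranked_methods$method_id[1L],
           "static_knn")

#' @rdname strategy
#' @param config [de_config()] for the per-fold weight learning.
#' @param seed Seed for the per-fold weight learning.
#' @export
strategy_dynamic_knn <- function(k = 5L, config = de_config(), seed = 42L) {
  s <- strategy("Dynamic-Learned-kNN",
                function(train_kb, fingerprint, weights)
                  recommend(fingerprint, train_kb, weights, k)$ranked_methods$method_id[1L],
                "dynamic_learned_knn")
  s$de_config <- config
  s$de_seed <- seed
  s
}

#' @rdname strategy
#' @param mcar_default,nonmcar_default,alpha See [two_rule_recommend()].
#' @export
strategy_two_rule <- function(mcar_default, nonmcar_default, alpha = 0.05)
  strategy("Two-rule",
           function(train_kb, fingerprint, weights) {
             p <- 10^(-unclass(fingerprint)["f11"])
             if (is.na(p) || p >= alpha) mcar_default else nonmcar_default
           }, "two_rule")

#' @rdname strategy
#' @export
strategy_oracle <- function() strategy("Oracle", NULL, "oracle")

#' Leakage-safe leave-one-dataset-out evaluation
#'
#' For each base group in turn, the training store is every instance from
#' all *other* groups (asserted on every fold: the intersection of
#' training base groups with the held-out group must be empty).
#' Dynamic-learned strategies re-learn their weights on each fold's
#' training store.  Each test instance is scored by its own
#' performance-vector entry for the chosen method; regret is the gap to
#' the per-instance oracle and a win is an exact oracle-method match.
#' Aggregates are instance-level means.  A strategy that returns a method
#' absent from a test instance's performance vector has that instance
#' skipped, with the incident counted in the report.
#'
#' @param kb A `knowledge_base` with >= 2 base groups.
#' @param strategies List of [strategy()] objects.
#' @param seed Integer seed (drives per-fold weight learning).
#' @return A list of class `evaluation_report`: `strategies` (per-strategy
#'   mean AUROC / regret / win rate), `per_condition`, `per_instance`
#'   (long table), `vbs_sbs`, `fold_log`, `incidents`, `fold_weights`.
#' @export
lodo_evaluate <- function(kb, strategies, seed = 42L) {
  if (!inherits(kb, "knowledge_base")) stop_param("kb must be a knowledge_base")
  groups <- kb_groups(kb)
  folds <- unique(groups)
  if (length(folds) < 2L) stop_param("need >= 2 base groups for LODO")
  n_methods <- length(kb$method_ids)

  rows <- list()
  incidents <- 0L
  fold_log <- list()
  fold_weights <- list()
  for (g in folds) {
    test_idx <- which(groups == g)
    train_idx <- which(groups != g)
    train_kb <- kb_subset(kb, train_idx)
    # Leakage assertion: the held-out group never reaches the training store.
    stopifnot(length(intersect(kb_groups(train_kb), g)) == 0L)
    fold_log[[g]] <- list(held_out = g, n_train = length(train_idx),
                          n_test = length(test_idx))

    needs_weights <- any(vapply(strategies, function(s)
      s$family == "dynamic_learned_knn", TRUE))
    w_fold <- NULL
    if (needs_weights) {
      dyn <- strategies[[which(vapply(strategies, function(s)
        s$family == "dynamic_learned_knn", TRUE))[1L]]]
      w_fold <- learn_weights(kb, exclude_group = g,
                              config = dyn$de_config %||% de_config(),
                              seed = dyn$de_seed %||% seed)$weights
      fold_weights[[g]] <- w_fold
    }

    for (ti in test_idx) {
      inst <- kb$instances[[ti]]
      pv <- inst$perf_vector
      for (s in strategies) {
        if (s$family == "random") {
          ok <- !is.na(pv)
          score <- mean(pv[ok])
          win <- mean(pv[ok] == inst$oracle_auroc)
          choice <- "<uniform>"
        } else if (s$family == "oracle") {
          choice <- inst$oracle_method
          score <- inst$oracle_auroc
          win <- 1
        } else {
          choice <- s$rule(train_kb, inst$fingerprint, w_fold)
          if (!choice %in% names(pv) || is.na(pv[choice])) {
            incidents <- incidents + 1L
            next
          }
          score <- unname(pv[choice])
          win <- as.numeric(choice == inst$oracle_method)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = s$name, instance_id = inst$instance_id,
          base_group = inst$base_group, condition = inst$condition,
          choice = choice, auroc = score,
          regret = inst$oracle_auroc - score, win = win)
      }
    }
  }
  per_instance <- do.call(rbind, rows)
  agg <- aggregate(cbind(auroc, regret, win) ~ strategy, per_instance, mean)
  names(agg) <- c("strategy", "mean_auroc", "mean_regret", "win_rate")
  per_cond <- aggregate(cbind(auroc, regret, win) ~ strategy + condition,
                        per_instance, mean)
  names(per_cond) <- c("strategy", "condition", "mean_auroc", "mean_regret", "win_rate")

  structure(list(strategies = agg[order(agg$mean_regret), ],
                 per_condition = per_cond,
                 per_instance = per_instance,
                 vbs_sbs = vbs_sbs_gap(kb),
                 fold_log = fold_log,
                 fold_weights = fold_weights,
                 incidents = incidents,
                 seed = as.integer(seed)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  df <- x$strategies
  df$mean_auroc <- sprintf("%.3f", df$mean_auroc)
  df$mean_regret <- sprintf("%.3f", df$mean_regret)
  df$win_rate <- sprintf("%.1f%%", 100 * df$win_rate)
  print(df, row.names = FALSE)
  cat(sprintf("VBS %.3f | SBS %.3f (%s) | gap %.3f | incidents %d\n",
              x$vbs_sbs$vbs, x$vbs_sbs$sbs, x$vbs_sbs$sbs_method,
              x$vbs_sbs$gap, x$incidents))
  invisible(x)
}

#' Virtual-best-solver / single-best-solver gap
#'
#' VBS = mean over instances of the per-instance best AUROC (oracle
#' selection); SBS = the best fixed method's mean AUROC.  Their gap bounds
#' what any selector can gain over the best default.  Partial performance
#' vectors are handled pairwise-complete (per-instance maxima and
#' per-method means each ignore missing entries).
#'
#' @param kb A `knowledge_base`.
#' @return A list: `vbs`, `sbs_method`, `sbs`, `gap`.
#' @export
vbs_sbs_gap <- function(kb) {
  perf <- kb_perf_matrix(kb)
  vbs <- mean(apply(perf, 1L, max, na.rm = TRUE))
  method_means <- colMeans(perf, na.rm = TRUE)
  sbs_method <- names(method_means)[order(-method_means, names(method_means))][1L]
  sbs <- unname(method_means[sbs_method])
  list(vbs = vbs, sbs_method = sbs_method, sbs = sbs, gap = vbs - sbs)
}

#' Decompose the oracle gap into noise and selection regret
#'
#' The total gap between the oracle and a recommender is split into a
#' noise component -- the expected amount by which the apparent best
#' method's resampled mean exceeds the true best mean under split
#' resampling (repetition variability) -- and a selection component, the
#' remainder (the cost of choosing a non-optimal method).  Both are
#' non-negative and sum exactly to the total gap; zero split variance
#' gives zero noise regret, and an oracle recommender gives zero
#' selection regret.
#'
#' @param kb A `knowledge_base` whose instances carry `perf_splits`.
#' @param recommendations Named character vector: instance_id -> chosen
#'   method id.
#' @param n_boot Bootstrap resamples of the split axis.
#' @param seed Integer seed.
#' @return A list: `total_gap`, `noise_regret`, `selection_regret`,
#'   `per_instance_noise`.
#' @export
decompose_oracle_gap <- function(kb, recommendations, n_boot = 200L, seed = 7L) {
  check_scalar(n_boot, "n_boot", lo = 10, integerish = TRUE)
  gaps <- noise <- numeric(length(kb$instances))
  for (i in seq_along(kb$instances)) {
    inst <- kb$instances[[i]]
    if (is.null(inst$perf_splits))
      stop_param("data-completeness error: instance ", inst$instance_id,
                 " has no per-split AUROCs")
    choice <- recommendations[[inst$instance_id]]
    if (is.null(choice) || !choice %in% names(inst$perf_vector))
      stop_param("no recommendation for instance ", inst$instance_id)
    gaps[i] <- inst$oracle_auroc - unname(inst$perf_vector[choice])
    sp <- inst$perf_splits
    ns <- ncol(sp)
    true_best <- max(rowMeans(sp))
    boot_max <- with_seed(child_seed(seed, i), {
      mean(vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(ns, ns, replace = TRUE)
        max(rowMeans(sp[, idx, drop = FALSE]))
      }, 0))
    })
    noise[i] <- max(boot_max - true_best, 0)
  }
  total <- mean(gaps)
  noise_regret <- min(mean(noise), total)
  list(total_gap = total,
       noise_regret = noise_regret,
       selection_regret = total - noise_regret,
       per_instance_noise = noise)
}

#' Friedman test for method complementarity
#'
#' Tests whether method performance rankings differ across conditions
#' (conditions are blocks, methods are treatments).  A significant result
#' means no single method dominates -- the premise of instance-adaptive
#' selection.
#'
#' @param perf Methods x conditions matrix of mean AUROCs, no missing
#'   cells, >= 3 methods and >= 2 conditions.
#' @return A list: `chi2`, `df`, `p`.
#' @export
friedman_complementarity <- function(perf) {
  perf <- as.matrix(perf)
  if (nrow(perf) < 3L || ncol(perf) < 2L)
    stop_param("need >= 3 methods and >= 2 conditions")
  if (anyNA(perf)) stop_param("completeness error: perf matrix has missing cells")
  ft <- friedman.test(t(perf))
  chi2 <- unname(ft$statistic)
  p <- ft$p.value
  if (!is.finite(chi2)) {
    # Complete ties in every block (identical methods): no evidence of
    # complementarity; the tie-corrected statistic is 0/0.
    chi2 <- 0
    p <- 1
  }
  list(chi2 = chi2, df = unname(ft$parameter), p = p)
}

#' Block bootstrap for a regret difference between two strategies
#'
#' Resamples base groups with replacement `B` times from an evaluation
#' report's per-instance table and recomputes the mean-regret difference
#' (strategy A minus strategy B) on each replicate.
#'
#' @param report An `evaluation_report` from [lodo_evaluate()].
#' @param strategy_a,strategy_b Strategy names as they appear in the
#'   report.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return A list: `delta` (observed difference), `ci` (2.5/97.5
#'   percentile interval), `B`, `seed`.
#' @export
block_bootstrap_delta <- function(report, strategy_a, strategy_b, B = 2000L,
                                  seed = 1L) {
  check_scalar(B, "B", lo = 2, integerish = TRUE)
  pi_df <- report$per_instance
  if (!all(c(strategy_a, strategy_b) %in% pi_df$strategy))
    stop_param("strategies not found in report: ", strategy_a, ", ", strategy_b)
  groups <- unique(pi_df$base_group)
  if (length(groups) < 2L)
    stop_param("degenerate resampling: need >= 2 base groups")
  by_group <- split(pi_df, pi_df$base_group)
  delta_of <- function(df) {
    mean(df$regret[df$strategy == strategy_a]) -
      mean(df$regret[df$strategy == strategy_b])
  }
  observed <- delta_of(pi_df)
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      take <- sample(groups, length(groups), replace = TRUE)
      delta_of(do.call(rbind, by_group[take]))
    }, 0)
  })
  list(delta = observed,
       ci = unname(quantile(reps, c(0.025, 0.975))),
       B = as.integer(B), seed = as.integer(seed))
}
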