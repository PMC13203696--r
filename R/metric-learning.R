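#' Weighted static fingerprint distance
#'
#' `d(a, b; w) = || w * (a - b) ||` over the ten structural dimensions
#' f1-f10.  The mechanism indicator f11 never enters any distance.
#'
#' @param fa,fb Fingerprints (named vectors containing `f1`...`f10`).
#' @param w A weight vector of length 10 (see [learn_weights()]); weights
#'   are used as given -- only distance *rankings* are invariant to
#'   positive rescaling.
#' @return A non-negative scalar.
#' @export
weighted_static_distance <- function(fa, fb, w) {
  dims <- sprintf("f%d", 1:10)
  if (!all(dims %in% names(fa)) || !all(dims %in% names(fb)))
    stop_param("fingerprint error: dimensions f1..f10 must be present")
  if (length(w) != 10L || any(w < 0)) stop_param("w must be 10 non-negative weights")
  sqrt(sum((w * (unclass(fa)[dims] - unclass(fb)[dims]))^2))
}

# Pairwise weighted static distances for a fingerprint matrix (rows =
# instances, columns = f1..f10), as a dist-ordered vector.
wsd_pairs <- function(fp, w) {
  as.vector(stats::dist(sweep(fp, 2L, w, `*`)))
}

#' Metric-learning objective
#'
#' The fitness of a candidate weight vector on a set of training
#' meta-instances: `-(0.7 * rho + 0.3 * r_match)`, where `rho` is the
#' Spearman rank correlation over all unordered instance pairs between the
#' weighted static distances and the dynamic (performance-vector)
#' distances, and `r_match` is the fraction of instances whose weighted
#' 1-nearest neighbour (self excluded) shares their oracle method.  A
#' constant distance vector makes `rho` undefined; it is treated as 0 with
#' a `rho_degenerate` attribute.
#'
#' @param w Length-10 non-negative weight vector.
#' @param training_instances List of >= 3 `meta_instance`s.
#' @return The scalar objective (lower is better) with attributes `rho`
#'   and `r_match`.
#' @export
ml_objective <- function(w, training_instances) {
  ctx <- ml_context(training_instances)
  ml_objective_ctx(w, ctx)
}

# Precompute everything that does not depend on w.
ml_context <- function(instances) {
  if (length(instances) < 3L)
    stop_param("sample-size error: need >= 3 training instances")
  fp <- t(vapply(instances, function(i) i$fingerprint[sprintf("f%d", 1:10)],
                 numeric(10)))
  n <- nrow(fp)
  # Column-major over (j < i) pairs, matching stats::dist ordering.
  dyn <- numeric(n * (n - 1) / 2)
  k <- 0L
  for (j in seq_len(n - 1L)) for (i in seq((j + 1L), n)) {
    k <- k + 1L
    dyn[k] <- dynamic_distance(instances[[j]], instances[[i]])
  }
  list(fp = fp,
       dyn = dyn,
       oracle = vapply(instances, `[[`, "", "oracle_method"),
       n = n)
}

ml_objective_ctx <- function(w, ctx) {
  if (length(w) != 10L || any(w < 0)) stop_param("w must be 10 non-negative weights")
  stat <- wsd_pairs(ctx$fp, w)
  rho <- spearman(stat, ctx$dyn)
  degenerate <- is.na(rho)
  if (degenerate) rho <- 0
  dm <- matrix(0, ctx$n, ctx$n)
  dm[lower.tri(dm)] <- stat
  dm <- dm + t(dm)
  diag(dm) <- Inf
  nn <- apply(dm, 1L, which.min)
  r_match <- mean(ctx$oracle[nn] == ctx$oracle)
  structure(-(0.7 * rho + 0.3 * r_match),
            rho = rho, r_match = r_match, rho_degenerate = degenerate)
}

#' Differential-evolution configuration
#'
#' Defaults follow the reference optimization contract: strategy best1bin,
#' population size 15, mutation factor dithered in (0.5, 1.0), crossover
#' rate 0.7, 500 iterations, convergence tolerance 1e-8.
#'
#' @param pop_size Population size multiplier; the population holds
#'   `pop_size * dimension` members (the convention of the reference
#'   optimizer).
#' @param mutation Length-2 dither range for the mutation factor.
#' @param crossover Crossover rate in \[0, 1\].
#' @param maxiter Maximum generations.
#' @param tol Relative convergence tolerance on population energies.
#' @return A `de_config` object.
#' @export
de_config <- function(pop_size = 15L, mutation = c(0.5, 1.0), crossover = 0.7,
                      maxiter = 500L, tol = 1e-8) {
  check_scalar(pop_size, "pop_size", lo = 5, integerish = TRUE)
  check_scalar(crossover, "crossover", lo = 0, hi = 1)
  check_scalar(maxiter, "maxiter", lo = 1, integerish = TRUE)
  check_scalar(tol, "tol", lo = 0)
  structure(list(pop_size = as.integer(pop_size), mutation = mutation,
                 crossover = crossover, maxiter = as.integer(maxiter), tol = tol),
            class = "de_config")
}

# Self-contained best1bin differential evolution (minimization) over box
# bounds, with per-generation mutation dither and scipy-style convergence
# (sd of population energies <= tol * |mean|).  pop_size follows the
# scipy convention: the population holds pop_size * dimension members.
de_best1bin <- function(fn, lower, upper, config, seed) {
  d <- length(lower)
  np <- config$pop_size * d
  with_seed(seed, {
    pop <- matrix(0, np, d)
    for (j in seq_len(d)) pop[, j] <- runif(np, lower[j], upper[j])
    energy <- apply(pop, 1L, fn)
    trace <- numeric(config$maxiter)
    for (gen in seq_len(config$maxiter)) {
      fmut <- runif(1, config$mutation[1], config$mutation[2])
      best <- pop[which.min(energy), ]
      for (i in seq_len(np)) {
        idx <- sample(setdiff(seq_len(np), i), 2L)
        mutant <- best + fmut * (pop[idx[1L], ] - pop[idx[2L], ])
        mutant <- pmin(pmax(mutant, lower), upper)
        cross <- runif(d) < config$crossover
        cross[sample.int(d, 1L)] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        e <- fn(trial)
        if (e <= energy[i]) {
          pop[i, ] <- trial
          energy[i] <- e
        }
      }
      trace[gen] <- min(energy)
      if (sd(energy) <= config$tol * abs(mean(energy)) + 1e-300) break
    }
    i_best <- which.min(energy)
    list(par = pop[i_best, ], value = energy[i_best],
         trace = trace[seq_len(gen)], generations = gen)
  })
}

#' Learn fingerprint weights from dynamic distances
#'
#' Maximizes agreement between weighted static fingerprint distances and
#' sweep-derived dynamic distances over the knowledge base, by
#' differential evolution (best1bin) on log10 weights with bounds
#' \[-3, 3\]^10; the returned weights are simplex-normalized (ranking is
#' invariant to positive rescaling, so normalization is presentation, not
#' optimization substance).  Instances from `exclude_group` are removed
#' before anything is computed -- the leakage guard of the LODO protocol.
#'
#' @param kb A `knowledge_base`.
#' @param exclude_group Optional base group to hold out entirely.
#' @param config A [de_config()].
#' @param seed Integer seed (42 by default, matching the reference
#'   contract).
#' @return A list of class `metric_learning_result`: `weights` (simplex),
#'   `rho`, `r_match`, `objective`, `de_trace`, `seed`, `n_train`.
#' @export
learn_weights <- function(kb, exclude_group = NULL, config = de_config(),
                          seed = 42L) {
  if (!inherits(kb, "knowledge_base")) stop_param("kb must be a knowledge_base")
  groups <- kb_groups(kb)
  keep <- if (is.null(exclude_group)) rep(TRUE, length(groups)) else
    groups != exclude_group
  if (sum(keep) < 3L)
    stop_param("sample-size error: fewer than 3 training instances after exclusion")
  train <- kb$instances[keep]
  stopifnot(!any(vapply(train, `[[`, "", "base_group") %in% exclude_group))
  ctx <- ml_context(train)
  fn <- function(v) as.numeric(ml_objective_ctx(10^v, ctx))
  fit <- de_best1bin(fn, rep(-3, 10), rep(3, 10), config, seed = seed)
  w_raw <- 10^fit$par
  w <- w_raw / sum(w_raw)
  obj <- ml_objective_ctx(w, ctx)
  structure(list(weights = setNames(w, sprintf("f%d", 1:10)),
                 rho = attr(obj, "rho"),
                 r_match = attr(obj, "r_match"),
                 objective = as.numeric(obj),
                 de_trace = fit$trace,
                 generations = fit$generations,
                 seed = as.integer(seed),
                 n_train = sum(keep)),
            class = "metric_learning_result")
}

#' @export
print.metric_learning_result <- function(x, ...) {
  cat(sprintf("<metric_learning_result> rho = %.4f, r_match = %.4f, objective = %.4f\n",
              x$rho, x$r_match, x$objective))
  top <- sort(x$weights, decreasing = TRUE)[1:3]
  cat("  top weights:", paste(sprintf("%s=%.2f", names(top), top), collapse = ", "),
      sprintf(" (n_train = %d, %d generations)\n", x$n_train, x$generations))
  invisible(x)
}
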