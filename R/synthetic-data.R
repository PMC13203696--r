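#' Generate a complete EHR-like dataset
#'
#' Draws an equicorrelated Gaussian feature block and a binary outcome from
#' a logistic model on those features.  This is the minimal model that
#' supports AUROC gradients (via `signal`) and imputation differences (via
#' `corr`): correlated features make conditional imputation informative,
#' and the logistic link gives every portfolio method a learnable signal.
#'
#' @param n Number of patients (>= 20).
#' @param f Number of features (>= 2).
#' @param imbalance Minority/majority class ratio in (0, 1]; 1 gives
#'   balanced classes.  The positive class is the minority.
#' @param corr Common pairwise feature correlation in \[0, 1).
#' @param signal Non-negative scale of the linear predictor; 0 gives a
#'   label independent of the features (null data).
#' @param seed Integer seed; same seed, same dataset.
#' @param dataset_id Identifier, defaults to `"synth-<seed>"`.
#'
#' @return A fully observed, fully labeled [clinical_matrix()].
#' @export
gen_complete_dataset <- function(n, f, imbalance = 1, corr = 0, signal = 1,
                                 seed, dataset_id = NULL) {
  check_scalar(n, "n", lo = 20, integerish = TRUE)
  check_scalar(f, "f", lo = 2, integerish = TRUE)
  check_scalar(imbalance, "imbalance", lo = 1e-6, hi = 1)
  if (corr < 0 || corr >= 1) stop_param("corr must be in [0, 1), got ", corr)
  check_scalar(signal, "signal", lo = 0)
  check_scalar(seed, "seed", integerish = TRUE)
  dataset_id <- dataset_id %||% sprintf("synth-%d", as.integer(seed))

  with_seed(seed, {
    # Equicorrelated block: shared factor + idiosyncratic noise.
    g <- rnorm(n)
    x <- sqrt(corr) * matrix(g, n, f) +
      sqrt(1 - corr) * matrix(rnorm(n * f), n, f)
    beta <- rep(1 / sqrt(f), f)
    eta <- as.vector(x %*% beta) * signal
    # Calibrate the intercept so the positive (minority) fraction matches
    # the requested imbalance ratio r: pi = r / (1 + r).
    target <- imbalance / (1 + imbalance)
    b0 <- if (signal == 0) qlogis(target) else
      uniroot(function(b) mean(plogis(b + eta)) - target,
              lower = -30, upper = 30)$root
    y <- rbinom(n, 1L, plogis(b0 + eta))
    clinical_matrix(x, y, dataset_id,
                    provenance = sprintf("gen_complete(seed=%d)", as.integer(seed)))
  })
}

#' Specification of a diagnosis -> procedure -> lab MAR chain
#'
#' Describes a conditional generative chain that yields missing-at-random
#' lab columns by construction: a patient's diagnosis determines which
#' procedures are ordered, and ordered procedures determine which lab
#' results are observed.  A lab value is absent because its procedure was
#' never ordered for that diagnosis -- masking depends on observed
#' variables only, never on the lab value itself.
#'
#' `proc_given_diag` and `lab_given_proc` hold independent Bernoulli
#' probabilities (ordering and trigger probabilities in \[0, 1\]), not
#' categorical rows: several procedures can be ordered for one patient,
#' and a lab is observed when at least one ordered procedure triggers it.
#'
#' @param diag_probs Probability vector over diagnoses (sums to 1).
#' @param proc_given_diag D x P matrix; entry (d, p) is the probability
#'   that procedure p is ordered given diagnosis d.
#' @param lab_given_proc P x L matrix; entry (p, l) is the probability
#'   that ordered procedure p triggers observation of lab l.
#' @param lab_value_params List with numeric vectors `mean` and `scale`
#'   (length L) for the underlying lab-value distributions, and optionally
#'   `diag_shift` (length D) adding a diagnosis-dependent mean shift.
#' @param outcome_coefficients Length-L effect sizes of the underlying lab
#'   values on the logistic outcome.
#'
#' @return A validated `mar_chain_spec` object.
#' @export
mar_chain_spec <- function(diag_probs, proc_given_diag, lab_given_proc,
                           lab_value_params, outcome_coefficients) {
  d <- length(diag_probs)
  if (d < 1L || any(diag_probs < 0) || abs(sum(diag_probs) - 1) > 1e-8)
    stop_param("diag_probs must be non-negative and sum to 1")
  proc_given_diag <- as.matrix(proc_given_diag)
  lab_given_proc <- as.matrix(lab_given_proc)
  if (nrow(proc_given_diag) != d)
    stop_param("proc_given_diag must have one row per diagnosis (", d, ")")
  if (nrow(lab_given_proc) != ncol(proc_given_diag))
    stop_param("lab_given_proc must have one row per procedure (",
               ncol(proc_given_diag), ")")
  if (any(proc_given_diag < 0 | proc_given_diag > 1) ||
      any(lab_given_proc < 0 | lab_given_proc > 1))
    stop_param("chain probabilities must lie in [0, 1]")
  l <- ncol(lab_given_proc)
  if (length(lab_value_params$mean) != l || length(lab_value_params$scale) != l)
    stop_param("lab_value_params$mean and $scale must have length ", l)
  if (any(lab_value_params$scale <= 0))
    stop_param("lab_value_params$scale must be positive")
  if (is.null(lab_value_params$diag_shift))
    lab_value_params$diag_shift <-
      if (d == 1L) 0 else seq(-0.5, 0.5, length.out = d)
  if (length(lab_value_params$diag_shift) != d)
    stop_param("lab_value_params$diag_shift must have length ", d)
  if (length(outcome_coefficients) != l)
    stop_param("outcome_coefficients must have length ", l)
  structure(list(n_diagnoses = d,
                 diag_probs = as.numeric(diag_probs),
                 proc_given_diag = proc_given_diag,
                 lab_given_proc = lab_given_proc,
                 lab_value_params = lab_value_params,
                 outcome_coefficients = as.numeric(outcome_coefficients)),
            class = "mar_chain_spec")
}

#' Default MAR chain specification
#'
#' A modest chain (3 diagnoses, 4 procedures, 6 labs) with ordering
#' probabilities spread over \[0.2, 0.95\] so per-lab missing rates are
#' heterogeneous and mechanism diagnostics are non-degenerate.
#'
#' @param seed Integer seed for drawing the chain probabilities.
#' @return A [mar_chain_spec()].
#' @export
default_mar_chain_spec <- function(seed = 101) {
  with_seed(seed, {
    d <- 3L; p <- 4L; l <- 6L
    diag_probs <- c(0.5, 0.3, 0.2)
    proc_given_diag <- matrix(runif(d * p, 0.2, 0.95), d, p)
    # Each lab is driven mainly by one procedure.
    lab_given_proc <- matrix(0.05, p, l)
    for (j in seq_len(l)) lab_given_proc[((j - 1) %% p) + 1L, j] <- 0.9
    mar_chain_spec(
      diag_probs, proc_given_diag, lab_given_proc,
      lab_value_params = list(mean = rnorm(l, 0, 1), scale = runif(l, 0.8, 1.5)),
      outcome_coefficients = rnorm(l, 0, 0.6))
  })
}

#' Generate a MAR-by-construction dataset from a conditional chain
#'
#' Columns are: one-hot diagnosis indicators (fully observed), procedure
#' indicators (fully observed), and lab values that are missing exactly
#' when no ordered procedure triggered them.  The pre-masking lab values
#' are retained in the `underlying` attribute so the MAR property can be
#' verified (within a diagnosis stratum, masked and observed underlying
#' values share a distribution).
#'
#' @param spec A [mar_chain_spec()].
#' @param n Number of patients (>= 50).
#' @param seed Integer seed.
#' @param dataset_id Identifier, defaults to `"mar-<seed>"`.
#'
#' @return A [clinical_matrix()] with attributes `underlying` (complete
#'   lab-value matrix), `lab_cols` (column indices of the labs) and
#'   `diagnosis` (integer diagnosis per patient).
#' @export
gen_mar_chain_dataset <- function(spec, n, seed, dataset_id = NULL) {
  if (!inherits(spec, "mar_chain_spec")) stop_param("spec must be a mar_chain_spec")
  check_scalar(n, "n", lo = 50, integerish = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  dataset_id <- dataset_id %||% sprintf("mar-%d", as.integer(seed))
  d <- spec$n_diagnoses
  p <- ncol(spec$proc_given_diag)
  l <- ncol(spec$lab_given_proc)

  with_seed(seed, {
    diag <- sample.int(d, n, replace = TRUE, prob = spec$diag_probs)
    proc <- matrix(rbinom(n * p, 1L, spec$proc_given_diag[diag, , drop = FALSE]),
                   n, p)
    # Lab l observed if any ordered procedure triggers it:
    # P(no trigger) = prod over ordered procs p of (1 - q_pl).
    p_none <- exp(proc %*% log(pmax(1 - spec$lab_given_proc, 1e-12)))
    observed <- matrix(runif(n * l), n, l) >= p_none
    labs <- matrix(rnorm(n * l), n, l) *
      rep(spec$lab_value_params$scale, each = n) +
      rep(spec$lab_value_params$mean, each = n) +
      spec$lab_value_params$diag_shift[diag]
    eta <- as.vector(labs %*% spec$outcome_coefficients)
    y <- rbinom(n, 1L, plogis(eta - mean(eta)))

    masked_labs <- labs
    masked_labs[!observed] <- NA_real_
    diag_oh <- matrix(0, n, d); diag_oh[cbind(seq_len(n), diag)] <- 1
    values <- cbind(diag_oh, proc, masked_labs)
    colnames(values) <- c(sprintf("diag%d", seq_len(d)),
                          sprintf("proc%d", seq_len(p)),
                          sprintf("lab%d", seq_len(l)))
    out <- clinical_matrix(values, y, dataset_id,
                           provenance = sprintf("gen_mar_chain(seed=%d)", as.integer(seed)))
    attr(out, "underlying") <- labs
    attr(out, "lab_cols") <- d + p + seq_len(l)
    attr(out, "diagnosis") <- diag
    out
  })
}

#' Generate a collection of base datasets with native missingness
#'
#' Emulates a multi-dataset library of EHR subsets with heterogeneous
#' native missing rates.  Native missingness is a mixture -- by default
#' 60\% MCAR cells and 40\% cells masked with probability increasing in an
#' always-observed driver feature (a MAR component) -- so that mechanism
#' diagnostics such as Little's test are non-degenerate.  Masking uses
#' exact cell counts, so each dataset's realized missing rate lands inside
#' `miss_range` by construction.
#'
#' @param n_datasets Number of datasets to generate.
#' @param size_range Length-2 integer range of patient counts.
#' @param miss_range Length-2 range of native missing rates, inside \[0, 1).
#' @param seed Integer seed.
#' @param f Number of features per dataset.
#' @param mar_frac Fraction of masked cells allocated to the MAR component.
#'
#' @return A list of [clinical_matrix()] objects with distinct
#'   `base_group` ids.
#' @export
gen_base_collection <- function(n_datasets, size_range = c(150L, 400L),
                                miss_range = c(0.04, 0.13), seed,
                                f = 27L, mar_frac = 0.4) {
  check_scalar(n_datasets, "n_datasets", lo = 1, integerish = TRUE)
  if (length(miss_range) != 2L || miss_range[1] < 0 || miss_range[2] >= 1 ||
      miss_range[1] > miss_range[2])
    stop_param("miss_range must be an increasing pair inside [0, 1)")
  if (length(size_range) != 2L || size_range[1] < 20 || size_range[1] > size_range[2])
    stop_param("size_range must be an increasing pair with minimum >= 20")
  check_scalar(mar_frac, "mar_frac", lo = 0, hi = 1)
  check_scalar(seed, "seed", integerish = TRUE)

  lapply(seq_len(n_datasets), function(i) {
    s <- child_seed(seed, i)
    with_seed(s, {
      n <- if (size_range[1] == size_range[2]) size_range[1] else
        sample(seq(size_range[1], size_range[2]), 1L)
      imb <- runif(1, 0.3, 0.8)
      corr <- runif(1, 0.1, 0.4)
      sig <- runif(1, 0.8, 2)
      m <- runif(1, miss_range[1], miss_range[2])
      gen_seed <- child_seed(s, 7)
      mask_seed <- child_seed(s, 11)
      id <- sprintf("base-%02d", i)
      data <- gen_complete_dataset(n, f, imbalance = imb, corr = corr,
                                   signal = sig, seed = gen_seed,
                                   dataset_id = id)
      data$base_group <- id
      with_seed(mask_seed, {
        total <- n * f
        k <- round(m * total)
        k_mcar <- round((1 - mar_frac) * k)
        k_mar <- k - k_mcar
        # Driver column 1 stays complete; its value drives the MAR part.
        eligible <- which(col(data$values) != 1L)
        mcar_cells <- sample(eligible, k_mcar)
        remaining <- setdiff(eligible, mcar_cells)
        driver <- data$values[, 1L]
        wts <- plogis(2 * scale(driver)[, 1L])[row(data$values)[remaining]]
        mar_cells <- remaining[sample.int(length(remaining), k_mar, prob = wts)]
        data$values[c(mcar_cells, mar_cells)] <- NA_real_
      })
      append_provenance(data, sprintf("native_missingness(rate=%.3f,mix=%.0f/%.0f)",
                                      m, 100 * (1 - mar_frac), 100 * mar_frac))
    })
  })
}

#' Specification of a planted-structure knowledge base
#'
#' Describes a synthetic meta-instance store in which the dynamic
#' (performance-vector) distances are, by construction, a fixed multiple of
#' the weighted static fingerprint distances under known `true_weights`
#' plus optional noise.  Used to verify that metric learning can recover
#' planted weights.
#'
#' @param n_instances Number of meta-instances.
#' @param n_methods Number of portfolio methods.
#' @param true_weights Length-10 non-negative simplex vector.
#' @param perf_noise_sd Standard deviation of performance noise.
#' @param n_groups Number of base groups (instances assigned round-robin).
#'
#' @return A validated `planted_kb_spec` object.
#' @export
planted_kb_spec <- function(n_instances, n_methods, true_weights,
                            perf_noise_sd = 0, n_groups = 5L) {
  check_scalar(n_instances, "n_instances", lo = 3, integerish = TRUE)
  # The exact isometry perf-space <- weighted-fingerprint-space needs at
  # least as many method axes as fingerprint dimensions.
  check_scalar(n_methods, "n_methods", lo = 10, integerish = TRUE)
  if (length(true_weights) != 10L || any(true_weights < 0) ||
      abs(sum(true_weights) - 1) > 1e-8)
    stop_param("true_weights must be a length-10 non-negative simplex vector")
  check_scalar(perf_noise_sd, "perf_noise_sd", lo = 0)
  check_scalar(n_groups, "n_groups", lo = 1, integerish = TRUE)
  structure(list(n_instances = as.integer(n_instances),
                 n_methods = as.integer(n_methods),
                 true_weights = as.numeric(true_weights),
                 perf_noise_sd = perf_noise_sd,
                 n_groups = as.integer(n_groups)),
            class = "planted_kb_spec")
}

#' Generate a planted-structure knowledge base
#'
#' Fingerprints are drawn uniformly in \[0, 1\]^10.  Performance vectors
#' are an isometric embedding of the weighted fingerprints: with `P` an
#' `n_methods x 10` matrix with orthonormal columns,
#' `perf_i = 0.62 + 0.25 * P (w * s_i) + noise`, so at zero noise the
#' Euclidean dynamic distance equals `0.25 *` the true-weighted static
#' distance exactly (Spearman correlation 1).
#'
#' @param spec A [planted_kb_spec()].
#' @param seed Integer seed.
#' @param n_splits If positive, also store per-method per-split AUROCs
#'   (mean-preserving jitter of `split_sd`), enabling oracle-gap
#'   decomposition tests.
#' @param split_sd Standard deviation of the per-split jitter.
#'
#' @return A `knowledge_base` object (see [build_kb()]) with attribute
#'   `true_weights`.
#' @export
gen_planted_kb <- function(spec, seed, n_splits = 0L, split_sd = 0.02) {
  if (!inherits(spec, "planted_kb_spec")) stop_param("spec must be a planted_kb_spec")
  check_scalar(seed, "seed", integerish = TRUE)
  m <- spec$n_methods
  n <- spec$n_instances
  method_ids <- sprintf("m%02d", seq_len(m))
  fp_names <- sprintf("f%d", 1:10)

  with_seed(seed, {
    fps <- matrix(runif(n * 10), n, 10, dimnames = list(NULL, fp_names))
    # Orthonormal columns: distances among P x equal distances among x.
    pm <- qr.Q(qr(matrix(rnorm(m * 10), m, 10)))
    z <- tcrossprod(sweep(fps, 2, spec$true_weights, `*`), pm)  # n x m
    perf <- 0.62 + 0.25 * z
    if (spec$perf_noise_sd > 0)
      perf <- perf + matrix(rnorm(n * m, 0, spec$perf_noise_sd), n, m)
    perf <- pmin(pmax(perf, 0.001), 0.999)
    f11 <- runif(n, 0, 2)

    instances <- lapply(seq_len(n), function(i) {
      pv <- setNames(perf[i, ], method_ids)
      splits <- NULL
      if (n_splits > 0L) {
        jitter <- matrix(rnorm(m * n_splits, 0, split_sd), m, n_splits)
        jitter <- jitter - rowMeans(jitter)   # mean-preserving
        splits <- matrix(pv, m, n_splits) + jitter
        dimnames(splits) <- list(method_ids, NULL)
      }
      meta_instance(
        instance_id = sprintf("pk-%03d", i),
        base_group = sprintf("g%02d", ((i - 1L) %% spec$n_groups) + 1L),
        condition = "planted",
        fingerprint = c(setNames(fps[i, ], fp_names), f11 = f11[i]),
        perf_vector = pv,
        perf_splits = splits)
    })
    kb <- new_knowledge_base(instances, method_ids,
                             grid = "planted",
                             provenance = sprintf("gen_planted_kb(seed=%d)", as.integer(seed)))
    attr(kb, "true_weights") <- spec$true_weights
    kb
  })
}
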