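#' Meta-instance: one characterized dataset in the knowledge base
#'
#' @param instance_id Unique identifier.
#' @param base_group Base-dataset group id (what LODO holds out).
#' @param condition Degradation condition tag.
#' @param fingerprint Named numeric vector with `f1`...`f10` and `f11`.
#' @param perf_vector Named per-method mean AUROC vector; `NA` marks a
#'   missing entry (partial sweep coverage).
#' @param perf_splits Optional methods x splits matrix of per-split AUROCs.
#' @return A `meta_instance` whose `oracle_method` / `oracle_auroc` are
#'   derived as the argmax of `perf_vector` (ties: lexicographic
#'   `method_id`).
#' @export
meta_instance <- function(instance_id, base_group, condition, fingerprint,
                          perf_vector, perf_splits = NULL) {
  fp_names <- sprintf("f%d", 1:11)
  if (!all(fp_names %in% names(fingerprint)))
    stop_param("fingerprint must contain named dimensions f1..f11")
  if (is.null(names(perf_vector)) || !length(perf_vector))
    stop_param("perf_vector must be a named numeric vector")
  ok <- !is.na(perf_vector)
  if (!any(ok)) stop_param("perf_vector has no non-missing entries")
  if (any(perf_vector[ok] < 0 | perf_vector[ok] > 1))
    stop_param("perf_vector entries must lie in [0, 1]")
  nm <- names(perf_vector)[ok]
  best <- nm[order(-perf_vector[ok], nm)][1L]
  structure(list(instance_id = as.character(instance_id),
                 base_group = as.character(base_group),
                 condition = as.character(condition),
                 fingerprint = unclass(fingerprint)[fp_names],
                 perf_vector = perf_vector,
                 perf_splits = perf_splits,
                 oracle_method = best,
                 oracle_auroc = unname(perf_vector[best])),
            class = "meta_instance")
}

new_knowledge_base <- function(instances, method_ids, grid = character(),
                               provenance = character()) {
  stopifnot(length(instances) > 0L)
  structure(list(instances = instances,
                 method_ids = method_ids,
                 grid = grid,
                 provenance = provenance,
                 version = "misselect-kb/1"),
            class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf("<knowledge_base> %d instances, %d methods, %d base groups\n",
              length(x$instances), length(x$method_ids),
              length(unique(kb_groups(x)))))
  invisible(x)
}

#' @export
length.knowledge_base <- function(x) length(x$instances)

kb_groups <- function(kb) vapply(kb$instances, `[[`, "", "base_group")

kb_fingerprints <- function(kb, dims = sprintf("f%d", 1:10)) {
  t(vapply(kb$instances, function(i) i$fingerprint[dims], numeric(length(dims))))
}

kb_perf_matrix <- function(kb) {
  t(vapply(kb$instances, function(i) {
    out <- setNames(rep(NA_real_, length(kb$method_ids)), kb$method_ids)
    out[names(i$perf_vector)] <- i$perf_vector
    out
  }, numeric(length(kb$method_ids))))
}

kb_subset <- function(kb, keep) {
  new_knowledge_base(kb$instances[keep], kb$method_ids, kb$grid, kb$provenance)
}

#' Constructive instance augmentation
#'
#' For each base dataset and each grid condition: physically degrade the
#' data, compute the static fingerprint f1-f10, and append f11 (Little's
#' MCAR test).  No model training happens here.  Returns exactly
#' `length(bases) * length(grid)` candidates; conditions that are
#' infeasible for a base (e.g. a missing-rate target below the native
#' rate) yield flagged candidates rather than failures.
#'
#' @param bases List of [clinical_matrix()] base datasets.
#' @param grid List of [degradation_condition()]s, e.g.
#'   [augmentation_grid()].
#' @param seed Integer base seed.
#' @param with_little Compute f11 via [littles_mcar_test()] (set `FALSE`
#'   to skip the EM and store `f11 = 0`).
#' @return A list of candidates: `dataset` (degraded [clinical_matrix()]
#'   or `NULL`), `base_group`, `condition`, `fingerprint` (with f11),
#'   `feasible`, `note`.
#' @export
augment_instances <- function(bases, grid, seed = 1L, with_little = TRUE) {
  if (!length(grid)) stop_param("grid must be non-empty")
  out <- list()
  k <- 0L
  for (b in seq_along(bases)) for (g in seq_along(grid)) {
    k <- k + 1L
    base <- bases[[b]]
    cond <- grid[[g]]
    cand <- tryCatch({
      degraded <- apply_condition(base, cond, seed = child_seed(seed, k))
      degraded$dataset_id <- paste0(base$dataset_id, "::", cond$tag)
      fp <- compute_fingerprint(degraded)
      p <- if (with_little) littles_mcar_test(degraded)$p_value else 1
      list(dataset = degraded, base_group = base$base_group,
           condition = cond$tag,
           fingerprint = c(unclass(fp), f11 = f11_from_p(p)),
           feasible = TRUE, note = "")
    }, error = function(e)
      list(dataset = NULL, base_group = base$base_group,
           condition = cond$tag, fingerprint = NULL,
           feasible = FALSE, note = conditionMessage(e)))
    out[[k]] <- cand
  }
  out
}

#' Exclusion rules for knowledge-base construction
#'
#' @param coverage_frac Minimum fraction of portfolio methods that must
#'   have sweep performance for a candidate to enter the store (default:
#'   all of them).
#' @param degeneracy_floor Minimum best-method mean AUROC; candidates
#'   whose best method performs below this are excluded as degenerate.
#' @return An `exclusion_rules` object.
#' @export
exclusion_rules <- function(coverage_frac = 1, degeneracy_floor = 0.55) {
  check_scalar(coverage_frac, "coverage_frac", lo = 0, hi = 1)
  check_scalar(degeneracy_floor, "degeneracy_floor", lo = 0, hi = 1)
  structure(list(coverage_frac = coverage_frac,
                 degeneracy_floor = degeneracy_floor),
            class = "exclusion_rules")
}

#' Build a knowledge base from augmentation candidates and sweep results
#'
#' Joins fingerprinted candidates with per-method sweep performance.
#' Candidates are excluded (with logged reasons) when they were infeasible,
#' when no sweep entry exists or method coverage falls below
#' `rules$coverage_frac` ("insufficient sweep coverage"), or when the best
#' available method's mean AUROC is below `rules$degeneracy_floor`
#' ("degenerate").  Exclusion is deterministic given the rules.
#'
#' @param candidates Output of [augment_instances()].
#' @param sweep_lookup Named list keyed `"<base_group>||<condition>"`,
#'   each entry a list with `perf` (named mean-AUROC vector) and
#'   optionally `splits` (methods x splits matrix).  See
#'   [sweep_lookup_from_sweeps()].
#' @param rules An [exclusion_rules()].
#' @return A `knowledge_base`; the exclusion log is in
#'   `attr(kb, "exclusions")`.
#' @export
build_kb <- function(candidates, sweep_lookup, rules = exclusion_rules()) {
  if (!inherits(rules, "exclusion_rules")) stop_param("rules must be exclusion_rules")
  method_ids <- sort(unique(unlist(lapply(sweep_lookup, function(e) names(e$perf)))))
  instances <- list()
  excl <- list()
  for (cand in candidates) {
    id <- paste0(cand$base_group, "::", cand$condition)
    if (!isTRUE(cand$feasible)) {
      excl[[length(excl) + 1L]] <- data.frame(candidate = id, reason = "infeasible condition")
      next
    }
    entry <- sweep_lookup[[paste(cand$base_group, cand$condition, sep = "||")]]
    covered <- if (is.null(entry)) 0 else mean(method_ids %in% names(entry$perf)[!is.na(entry$perf)])
    if (is.null(entry) || covered < rules$coverage_frac - 1e-12) {
      excl[[length(excl) + 1L]] <- data.frame(candidate = id, reason = "insufficient sweep coverage")
      next
    }
    if (max(entry$perf, na.rm = TRUE) < rules$degeneracy_floor) {
      excl[[length(excl) + 1L]] <- data.frame(candidate = id, reason = "degenerate")
      next
    }
    instances[[length(instances) + 1L]] <- meta_instance(
      instance_id = id, base_group = cand$base_group,
      condition = cand$condition, fingerprint = cand$fingerprint,
      perf_vector = entry$perf, perf_splits = entry$splits)
  }
  if (!length(instances))
    stop_param("empty store: every candidate was excluded")
  kb <- new_knowledge_base(instances, method_ids,
                           grid = unique(vapply(candidates, `[[`, "", "condition")))
  attr(kb, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(candidate = character(), reason = character())
  kb
}

#' Build a sweep lookup table from sweep results
#'
#' Maps each base group and named condition to the per-method mean AUROCs
#' (and per-split AUROCs) of the sweep cell matching that condition's
#' missing-rate/label-rate/mechanism coordinates.
#'
#' @param sweeps List of `sweep_result`s (one per base dataset).
#' @param grid List of [degradation_condition()]s naming the conditions.
#' @return A named list suitable for [build_kb()].
#' @export
sweep_lookup_from_sweeps <- function(sweeps, grid) {
  lookup <- list()
  for (sw in sweeps) {
    native <- NULL
    for (cond in grid) {
      # A natural condition keeps the native rate: match the smallest
      # covered miss rate instead of the injection target.
      target_mech <- if (cond$mechanism == "natural") "MCAR" else cond$mechanism
      keys <- names(sw$cells)
      match_key <- NULL
      if (cond$mechanism == "natural" || cond$miss_target == 0) {
        cand <- keys[grepl(paste0("^", target_mech, "\\|"), keys)]
        covered <- cand[vapply(cand, function(k) isTRUE(sw$cells[[k]]$covered), TRUE)]
        covered <- covered[vapply(covered, function(k)
          abs(sw$cells[[k]]$condition$label - cond$label_rate) < 1e-9, TRUE)]
        if (length(covered)) {
          miss <- vapply(covered, function(k) sw$cells[[k]]$condition$miss, 0)
          match_key <- covered[which.min(miss)]
        }
      } else {
        k <- cell_key(cond$miss_target, cond$label_rate, cond$mechanism)
        if (!is.null(sw$cells[[k]]) && isTRUE(sw$cells[[k]]$covered)) match_key <- k
      }
      if (is.null(match_key)) next
      cell <- sw$cells[[match_key]]
      perf <- vapply(cell$results, function(r) r$mean_auroc, 0)
      splits <- t(vapply(cell$results, function(r) r$per_split_auroc,
                         numeric(length(cell$results[[1L]]$per_split_auroc))))
      rownames(splits) <- names(perf)
      lookup[[paste(sw$base_group, cond$tag, sep = "||")]] <-
        list(perf = perf, splits = splits)
    }
  }
  lookup
}

#' Write / read a knowledge base as structured text
#'
#' The store is one versioned JSON document with instances as records;
#' fingerprints and performance vectors are named fields, and missing
#' performance entries round-trip as nulls.  [kb_read()] validates the
#' version and the performance ranges and names the offending record on
#' failure.
#'
#' @param kb A `knowledge_base`.
#' @param path File path.
#' @return `kb_write` returns `path` invisibly; `kb_read` the
#'   reconstructed `knowledge_base`.
#' @export
kb_write <- function(kb, path) {
  doc <- list(
    version = kb$version,
    method_ids = kb$method_ids,
    grid = kb$grid,
    provenance = kb$provenance,
    instances = lapply(kb$instances, function(i) {
      rec <- list(instance_id = i$instance_id, base_group = i$base_group,
                  condition = i$condition,
                  fingerprint = as.list(i$fingerprint),
                  perf_vector = as.list(i$perf_vector))
      if (!is.null(i$perf_splits))
        rec$perf_splits <- setNames(
          lapply(seq_len(nrow(i$perf_splits)),
                 function(r) as.numeric(i$perf_splits[r, ])),
          rownames(i$perf_splits))
      rec
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname kb_write
#' @export
kb_read <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$version, "misselect-kb/1"))
    stop_param("format error: unsupported store version ", doc$version %||% "<missing>")
  method_ids <- unlist(doc$method_ids)
  instances <- lapply(doc$instances, function(rec) {
    id <- rec$instance_id %||% "<unnamed>"
    fp <- vapply(rec$fingerprint, function(v) v %||% NA_real_, 0)
    pv <- vapply(rec$perf_vector, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
    ok <- !is.na(pv)
    if (any(pv[ok] < 0 | pv[ok] > 1))
      stop_param("format error: perf value outside [0, 1] in record ", id)
    splits <- NULL
    if (!is.null(rec$perf_splits)) {
      splits <- do.call(rbind, lapply(rec$perf_splits, function(r) unlist(r)))
      rownames(splits) <- names(rec$perf_splits)
    }
    meta_instance(id, rec$base_group, rec$condition, fp, pv, splits)
  })
  new_knowledge_base(instances, method_ids,
                     grid = unlist(doc$grid) %||% character(),
                     provenance = unlist(doc$provenance) %||% character())
}
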