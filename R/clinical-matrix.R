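#' Patient-by-feature table with missing cells and partial labels
#'
#' The basic data container of the toolkit: a numeric matrix of patients
#' (rows) by features (columns) in which `NA` marks an unobserved cell, plus
#' a label vector over \{0, 1, [unlabeled_sentinel()]\}.  `base_group` ties
#' together all quality-perturbed versions of one base dataset and is what
#' the leave-one-dataset-out evaluation holds out.
#'
#' @param values Numeric matrix, patients in rows, features in columns.
#'   `NA` denotes a missing cell.
#' @param labels Vector of length `nrow(values)` over 0, 1 and the
#'   unlabeled sentinel.
#' @param dataset_id Character identifier of this dataset.
#' @param base_group Character identifier shared by all perturbed versions
#'   of one base dataset; defaults to `dataset_id`.
#' @param provenance Character vector of free-form tags describing how the
#'   dataset was produced.
#'
#' @return An object of class `clinical_matrix` with fields `values`,
#'   `labels`, `dataset_id`, `base_group`, `provenance`.
#' @export
clinical_matrix <- function(values, labels, dataset_id,
                            base_group = dataset_id,
                            provenance = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_param("values must be a numeric matrix")
  n <- nrow(values); f <- ncol(values)
  if (n < 1L || f < 1L) stop_param("values must have at least 1 row and 1 column")
  labels <- as.integer(labels)
  if (length(labels) != n)
    stop_param("labels must have one entry per row (", n, "), got ", length(labels))
  if (!all(labels %in% c(0L, 1L, UNLABELED)))
    stop_param("labels may only contain 0, 1 and the unlabeled sentinel ", UNLABELED)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("x%02d", seq_len(f))
  out <- structure(
    list(values = values, labels = labels,
         dataset_id = as.character(dataset_id),
         base_group = as.character(base_group),
         provenance = as.character(provenance)),
    class = "clinical_matrix")
  out
}

#' @export
print.clinical_matrix <- function(x, ...) {
  n <- nrow(x$values); f <- ncol(x$values)
  miss <- mean(is.na(x$values))
  lab <- mean(x$labels != UNLABELED)
  cat(sprintf("<clinical_matrix> %s  (%d patients x %d features)\n",
              x$dataset_id, n, f))
  cat(sprintf("  base group: %s | missing: %.1f%% | labeled: %.1f%%\n",
              x$base_group, 100 * miss, 100 * lab))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.clinical_matrix <- function(x) dim(x$values)

# Rows where every feature is missing (flagged, per the container contract).
fully_missing_rows <- function(data) {
  which(rowSums(!is.na(data$values)) == 0L)
}

global_missing_rate <- function(data) mean(is.na(data$values))

labeled_fraction <- function(data) mean(data$labels != UNLABELED)

append_provenance <- function(data, tag) {
  data$provenance <- c(data$provenance, tag)
  data
}

#' Write / read a dataset as delimited text
#'
#' Datasets are exported as a comma-delimited table (header row; empty
#' string for a missing cell; label column named `label` with the unlabeled
#' sentinel written literally) plus a JSON sidecar `<path>.meta.json`
#' holding `dataset_id`, `base_group` and provenance tags.
#'
#' @param data A [clinical_matrix()].
#' @param path File path for the delimited table.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the reconstructed [clinical_matrix()].
#' @export
write_dataset <- function(data, path) {
  df <- as.data.frame(data$values)
  df$label <- data$labels
  utils::write.csv(df, path, row.names = FALSE, na = "")
  meta <- list(dataset_id = data$dataset_id,
               base_group = data$base_group,
               provenance = as.list(data$provenance))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df))
    stop_param("dataset file has no `label` column: ", path)
  labels <- as.integer(df$label)
  values <- as.matrix(df[setdiff(names(df), "label")])
  storage.mode(values) <- "double"
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    clinical_matrix(values, labels, meta$dataset_id,
                    meta$base_group %||% meta$dataset_id,
                    unlist(meta$provenance) %||% character())
  } else {
    clinical_matrix(values, labels, basename(path))
  }
}
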