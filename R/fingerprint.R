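#' Compute the static missingness fingerprint (f1-f10)
#'
#' Ten structural dimensions of a dataset's missing-data profile, each in
#' \[0, 1\], covering amount (f1 global rate, f3 cross-feature variance of
#' per-feature rates normalized by the maximal Bernoulli variance 0.25,
#' f4 per-feature maximum), structure (f5/f6 mean and max absolute Pearson
#' correlation between mask columns, f7 absolute correlation between
#' per-row missing count and the label), task descriptors (f2 labeled
#' fraction, f8 minority/majority class ratio), and diversity (f9 unique
#' missingness patterns / N, f10 dominant pattern fraction).
#'
#' Degenerate cases follow fixed rules: mask columns with zero variance
#' (features always or never missing) are excluded from f5/f6 pairs and
#' both default to 0 when no valid pair remains; f7 is computed over
#' labeled rows only and is 0 when either side is constant; f8 is 0 when a
#' class is absent.
#'
#' The eleventh dimension (Little's MCAR test) is *not* computed here; see
#' [littles_mcar_test()] and [f11_from_p()].  It never enters recommender
#' distances.
#'
#' @param data A [clinical_matrix()] with at least 2 rows and 2 columns.
#' @return A named numeric vector `f1`...`f10` of class `fingerprint`,
#'   with attribute `n` (row count, relevant when comparing f9 across
#'   datasets of different size).
#' @export
compute_fingerprint <- function(data) {
  if (!inherits(data, "clinical_matrix")) stop_param("data must be a clinical_matrix")
  x <- data$values
  n <- nrow(x); f <- ncol(x)
  if (n < 2L || f < 2L) stop_param("fingerprint needs at least 2 rows and 2 columns")
  mask <- is.na(x)
  if (all(mask)) stop_param("degenerate input: all cells are missing")

  col_miss <- colMeans(mask)
  f1 <- mean(mask)
  f2 <- mean(data$labels != UNLABELED)
  # Population variance of per-feature missing rates, scaled by the
  # maximal Bernoulli variance 0.25 so the extreme {0,1} profile maps to 1.
  f3 <- mean((col_miss - mean(col_miss))^2) / 0.25
  f4 <- max(col_miss)

  keep <- col_miss > 0 & col_miss < 1
  if (sum(keep) >= 2L) {
    cm <- abs(cor(mask[, keep, drop = FALSE] * 1))
    off <- cm[upper.tri(cm)]
    f5 <- mean(off); f6 <- max(off)
  } else {
    f5 <- 0; f6 <- 0
  }

  labeled <- data$labels != UNLABELED
  rowmiss <- rowSums(mask)
  f7 <- 0
  if (sum(labeled) >= 2L) {
    yl <- data$labels[labeled]; rl <- rowmiss[labeled]
    if (sd(yl) > 0 && sd(rl) > 0) f7 <- abs(cor(rl, yl))
  }
  n1 <- sum(data$labels == 1L); n0 <- sum(data$labels == 0L)
  f8 <- if (n1 == 0L || n0 == 0L) 0 else min(n1, n0) / max(n1, n0)

  pat <- apply(mask, 1L, function(r) paste(as.integer(r), collapse = ""))
  tab <- table(pat)
  f9 <- length(tab) / n
  f10 <- max(tab) / n

  structure(c(f1 = f1, f2 = f2, f3 = f3, f4 = f4, f5 = f5,
              f6 = f6, f7 = f7, f8 = f8, f9 = f9, f10 = f10),
            class = "fingerprint", n = n)
}

#' Mechanism indicator from Little's test p-value
#'
#' Maps a p-value to the stored fingerprint dimension f11 as
#' `-log10(max(p, 1e-300))`; the floor keeps numerically-zero p-values
#' finite.
#'
#' @param p A probability in \[0, 1\].
#' @return A non-negative scalar.
#' @export
f11_from_p <- function(p) {
  check_scalar(p, "p", lo = 0, hi = 1)
  -log10(max(p, 1e-300))
}
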