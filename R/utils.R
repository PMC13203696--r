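#' @importFrom stats cor var rnorm runif rbinom qlogis plogis pchisq sd
#'   quantile uniroot aggregate friedman.test ks.test setNames
#' @importFrom utils head
NULL

# Sentinel marking unlabeled rows.  Labels live in {0, 1, UNLABELED}.
UNLABELED <- -1L

#' Unlabeled-row sentinel
#'
#' The reserved label value marking rows whose outcome is unknown (for
#' example after label trimming).  Distinct from the 0/1 outcome codes and
#' written literally when datasets are exported as delimited text.
#'
#' @return The integer sentinel, `-1L`.
#' @export
unlabeled_sentinel <- function() UNLABELED

stop_param <- function(...) {
  stop(structure(class = c("misselect_param_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar <- function(x, name, lo = -Inf, hi = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_param(name, " must be a single non-missing number")
  if (x < lo || x > hi)
    stop_param(name, " must be in [", lo, ", ", hi, "], got ", x)
  if (integerish && x != round(x))
    stop_param(name, " must be a whole number, got ", x)
  invisible(x)
}

# Evaluate `expr` under a private RNG stream; the caller's RNG state is
# untouched, so all randomness flows from the explicit per-call seed.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a base seed and an index, kept inside 32-bit
# integer range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 9973) %% 2147483647)
}

# Rank-based AUROC of scores against 0/1 labels (equivalent to the
# Mann-Whitney statistic; ties get average rank credit).
auroc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

brier <- function(scores, labels) {
  mean((scores - labels)^2)
}

# Shannon entropy in bits of a vector of counts or probabilities.
entropy_bits <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Spearman correlation with average-rank ties; returns NA if either side is
# constant.
spearman <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(rank(x), rank(y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
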