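#' Little's MCAR test
#'
#' Tests whether the observed missingness pattern is consistent with
#' missing-completely-at-random.  Rows are grouped by missingness pattern;
#' the grand mean and covariance are estimated by expectation-maximization
#' under a multivariate normal model; and the statistic
#' \deqn{d^2 = \sum_j n_j (\bar y_{j,obs} - \hat\mu_{j,obs})^\top
#'       \hat\Sigma_{j,obs}^{-1} (\bar y_{j,obs} - \hat\mu_{j,obs})}
#' is referred to a chi-square distribution with
#' \eqn{df = \sum_j p_j - F} degrees of freedom, where \eqn{p_j} is the
#' number of observed variables in pattern \eqn{j}.
#'
#' Numerics: EM runs at most `max_iter` iterations and stops when the
#' largest parameter change falls below `tol`; a ridge of `1e-8` is added
#' to covariance diagonals before inversion; fully missing rows are
#' dropped; zero-variance columns are dropped (with `F` adjusted).  A
#' single observed pattern, or `df <= 0`, yields `p = 1` with
#' `n_patterns` reported.
#'
#' @param data A [clinical_matrix()] (labels are ignored).
#' @param max_iter Maximum EM iterations.
#' @param tol EM convergence tolerance on the parameter change.
#' @return A list of class `mcar_test_result` with fields `statistic`,
#'   `df`, `p_value`, `n_patterns`, `converged`.
#' @export
littles_mcar_test <- function(data, max_iter = 100L, tol = 1e-6) {
  if (!inherits(data, "clinical_matrix")) stop_param("data must be a clinical_matrix")
  x <- data$values
  if (!is.numeric(x)) stop("non-numeric data matrix")
  x <- x[rowSums(!is.na(x)) > 0L, , drop = FALSE]
  # Drop zero-variance columns (constant observed values carry no
  # information for the normal-model test).
  obs_var <- apply(x, 2L, function(v) stats::var(v[!is.na(v)]))
  x <- x[, !is.na(obs_var) & obs_var > 0, drop = FALSE]
  n <- nrow(x); f <- ncol(x)
  if (n < 2L || f < 1L)
    return(mcar_result(0, 0L, 1, 1L, TRUE))

  pat_key <- apply(is.na(x), 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat_key)
  n_patterns <- length(groups)
  df <- sum(vapply(groups, function(idx) sum(!is.na(x[idx[1L], ])), 0)) - f
  if (n_patterns < 2L || df <= 0L)
    return(mcar_result(0, max(df, 0L), 1, n_patterns, TRUE))

  em <- em_mvnorm(x, groups, max_iter = max_iter, tol = tol)

  d2 <- 0
  for (idx in groups) {
    obs <- which(!is.na(x[idx[1L], ]))
    ybar <- colMeans(x[idx, obs, drop = FALSE])
    dev <- ybar - em$mu[obs]
    sig <- em$sigma[obs, obs, drop = FALSE]
    diag(sig) <- diag(sig) + 1e-8
    d2 <- d2 + length(idx) * drop(crossprod(dev, solve(sig, dev)))
  }
  mcar_result(d2, df, pchisq(d2, df, lower.tail = FALSE), n_patterns, em$converged)
}

mcar_result <- function(statistic, df, p, n_patterns, converged) {
  structure(list(statistic = statistic, df = as.integer(df), p_value = p,
                 n_patterns = as.integer(n_patterns), converged = converged),
            class = "mcar_test_result")
}

#' @export
print.mcar_test_result <- function(x, ...) {
  cat(sprintf("Little's MCAR test: d2 = %.4f, df = %d, p = %.4g (%d patterns%s)\n",
              x$statistic, x$df, x$p_value, x$n_patterns,
              if (x$converged) "" else ", EM not converged"))
  invisible(x)
}

# EM for the multivariate normal with missing data, vectorized over
# missingness-pattern groups.  Returns ML estimates (covariance divided by
# n) of the grand mean and covariance.
em_mvnorm <- function(x, groups = NULL, max_iter = 100L, tol = 1e-6) {
  n <- nrow(x); f <- ncol(x)
  if (is.null(groups)) {
    pat_key <- apply(is.na(x), 1L, function(r) paste(as.integer(r), collapse = ""))
    groups <- split(seq_len(n), pat_key)
  }
  mu <- vapply(seq_len(f), function(j) mean(x[, j], na.rm = TRUE), 0)
  sigma <- diag(vapply(seq_len(f), function(j) {
    v <- stats::var(x[, j], na.rm = TRUE); if (is.na(v) || v <= 0) 1 else v
  }, 0), f)

  converged <- FALSE
  for (it in seq_len(max_iter)) {
    t1 <- numeric(f)
    t2 <- matrix(0, f, f)
    for (idx in groups) {
      obs <- which(!is.na(x[idx[1L], ]))
      mis <- setdiff(seq_len(f), obs)
      xo <- x[idx, obs, drop = FALSE]
      ni <- length(idx)
      if (length(mis) == 0L) {
        t1[obs] <- t1[obs] + colSums(xo)
        t2[obs, obs] <- t2[obs, obs] + crossprod(xo)
        next
      }
      so <- sigma[obs, obs, drop = FALSE]
      diag(so) <- diag(so) + 1e-8
      b <- solve(so, sigma[obs, mis, drop = FALSE])        # |obs| x |mis|
      dev <- sweep(xo, 2L, mu[obs])
      xm <- matrix(mu[mis], ni, length(mis), byrow = TRUE) + dev %*% b
      cond_cov <- sigma[mis, mis, drop = FALSE] -
        crossprod(sigma[obs, mis, drop = FALSE], b)
      xi <- matrix(NA_real_, ni, f)
      xi[, obs] <- xo
      xi[, mis] <- xm
      t1 <- t1 + colSums(xi)
      t2 <- t2 + crossprod(xi)
      t2[mis, mis] <- t2[mis, mis] + ni * cond_cov
    }
    mu_new <- t1 / n
    sigma_new <- t2 / n - tcrossprod(mu_new)
    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma))
    mu <- mu_new
    sigma <- (sigma_new + t(sigma_new)) / 2
    if (delta < tol) { converged <- TRUE; break }
  }
  list(mu = mu, sigma = sigma, converged = converged)
}
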