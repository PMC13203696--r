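# Reference pipeline portfolio: lightweight impute+classify and
# end-to-end methods behind a uniform fit/predict contract.
#
# The classifier backbone is a self-contained gradient-boosted stump
# learner with logistic loss.  Missing values get a learned default
# direction per split (the side with the larger gain), which doubles as
# the "native missing" end-to-end method.

# ---- gradient-boosted stumps -------------------------------------------

boost_fit <- function(x, y, n_rounds = 40L, shrinkage = 0.3, lambda = 1) {
  n <- nrow(x); f <- ncol(x)
  p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  f0 <- log(p0 / (1 - p0))
  pred <- rep(f0, n)
  # Presort each column once; NA indices kept separately.
  ord <- vector("list", f)
  for (j in seq_len(f)) {
    obs <- which(!is.na(x[, j]))
    ord[[j]] <- obs[order(x[obs, j])]
  }
  trees <- vector("list", n_rounds)
  n_used <- 0L
  for (round in seq_len(n_rounds)) {
    p <- plogis(pred)
    g <- p - y
    h <- pmax(p * (1 - p), 1e-12)
    gt <- sum(g); ht <- sum(h)
    base_score <- gt^2 / (ht + lambda)
    best <- list(gain = 1e-12)
    for (j in seq_len(f)) {
      oj <- ord[[j]]
      nj <- length(oj)
      if (nj < 2L) next
      gna <- gt - sum(g[oj]); hna <- ht - sum(h[oj])
      cg <- cumsum(g[oj]); ch <- cumsum(h[oj])
      vx <- x[oj, j]
      valid <- which(vx[-nj] < vx[-1L])   # split between distinct values
      if (!length(valid)) next
      gl <- cg[valid]; hl <- ch[valid]
      # Missing values routed right:
      gain_r <- gl^2 / (hl + lambda) + (gt - gl)^2 / (ht - hl + lambda) - base_score
      # Missing values routed left:
      gl2 <- gl + gna; hl2 <- hl + hna
      gain_l <- gl2^2 / (hl2 + lambda) + (gt - gl2)^2 / (ht - hl2 + lambda) - base_score
      kr <- which.max(gain_r); kl <- which.max(gain_l)
      if (gain_r[kr] >= gain_l[kl]) {
        if (gain_r[kr] > best$gain)
          best <- list(gain = gain_r[kr], feature = j, na_left = FALSE,
                       threshold = (vx[valid[kr]] + vx[valid[kr] + 1L]) / 2,
                       gl = gl[kr], hl = hl[kr])
      } else if (gain_l[kl] > best$gain) {
        best <- list(gain = gain_l[kl], feature = j, na_left = TRUE,
                     threshold = (vx[valid[kl]] + vx[valid[kl] + 1L]) / 2,
                     gl = gl2[kl], hl = hl2[kl])
      }
    }
    if (is.null(best$feature)) break
    wl <- -best$gl / (best$hl + lambda)
    wr <- -(gt - best$gl) / (ht - best$hl + lambda)
    xj <- x[, best$feature]
    left <- !is.na(xj) & xj < best$threshold
    if (best$na_left) left <- left | is.na(xj)
    pred <- pred + shrinkage * ifelse(left, wl, wr)
    trees[[round]] <- list(feature = best$feature, threshold = best$threshold,
                           na_left = best$na_left,
                           wl = shrinkage * wl, wr = shrinkage * wr)
    n_used <- round
  }
  structure(list(f0 = f0, trees = trees[seq_len(n_used)]), class = "boost_model")
}

boost_predict <- function(model, x) {
  pred <- rep(model$f0, nrow(x))
  for (tr in model$trees) {
    xj <- x[, tr$feature]
    left <- !is.na(xj) & xj < tr$threshold
    if (tr$na_left) left <- left | is.na(xj)
    pred <- pred + ifelse(left, tr$wl, tr$wr)
  }
  plogis(pred)
}

# ---- imputers -----------------------------------------------------------

train_col_means <- function(x) {
  m <- colMeans(x, na.rm = TRUE)
  m[is.nan(m)] <- 0
  m
}

fill_means <- function(x, means) {
  idx <- which(is.na(x))
  if (length(idx)) x[idx] <- means[col(x)[idx]]
  x
}

impute_knn <- function(train, test, k = 5L) {
  means <- train_col_means(train)
  sds <- apply(train, 2L, sd, na.rm = TRUE)
  sds[is.na(sds) | sds == 0] <- 1
  ref <- sweep(fill_means(train, means), 2L, means)
  ref <- sweep(ref, 2L, sds, `/`)
  fill_one <- function(x) {
    q <- sweep(fill_means(x, means), 2L, means)
    q <- sweep(q, 2L, sds, `/`)
    out <- x
    rows <- which(rowSums(is.na(x)) > 0L)
    for (i in rows) {
      d2 <- colSums((t(ref) - q[i, ])^2)
      nb <- order(d2)[seq_len(min(k, length(d2)))]
      mis <- which(is.na(x[i, ]))
      for (j in mis) {
        v <- train[nb, j]
        out[i, j] <- if (all(is.na(v))) means[j] else mean(v, na.rm = TRUE)
      }
    }
    out
  }
  list(train = fill_one(train), test = fill_one(test))
}

# Iterative chained-equations imputation with per-column linear models.
# Coefficients fitted on the training data are reused on the test data.
impute_chained <- function(train, test, n_iter = 2L) {
  means <- train_col_means(train)
  tr <- fill_means(train, means)
  te <- fill_means(test, means)
  mis_tr <- is.na(train); mis_te <- is.na(test)
  cols <- which(colSums(mis_tr) > 0L | colSums(mis_te) > 0L)
  for (it in seq_len(n_iter)) {
    for (j in cols) {
      obs <- which(!mis_tr[, j])
      if (length(obs) < ncol(train) + 2L) next
      xo <- cbind(1, tr[obs, -j, drop = FALSE])
      fit <- tryCatch(stats::.lm.fit(xo, train[obs, j]), error = function(e) NULL)
      if (is.null(fit)) next
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      if (any(mis_tr[, j]))
        tr[mis_tr[, j], j] <- cbind(1, tr[mis_tr[, j], -j, drop = FALSE]) %*% beta
      if (any(mis_te[, j]))
        te[mis_te[, j], j] <- cbind(1, te[mis_te[, j], -j, drop = FALSE]) %*% beta
    }
  }
  list(train = tr, test = te)
}

# ---- logistic regression backbone --------------------------------------

logit_fit_predict <- function(xtr, ytr, xte) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, xtr), ytr, family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  as.vector(plogis(cbind(1, xte) %*% beta))
}

# ---- the portfolio ------------------------------------------------------

new_pipeline_method <- function(method_id, fit_predict) {
  structure(list(method_id = method_id, fit_predict = fit_predict),
            class = "pipeline_method")
}

#' @export
print.pipeline_method <- function(x, ...) {
  cat("<pipeline_method>", x$method_id, "\n"); invisible(x)
}

#' Reference pipeline portfolio
#'
#' Six lightweight methods spanning the impute+classify and end-to-end
#' paradigms: mean-impute + logistic regression, missing-indicator
#' augmented logistic regression, and four gradient-boosted-stump
#' pipelines (mean impute, kNN impute, iterative chained impute, and
#' native missing-value handling via learned default split directions).
#' All methods are deterministic given the fit seed and tolerate any
#' missing rate below 1 per column.  Deep and graph methods are out of
#' scope here; the `pipeline_method` contract (a `fit_predict(train_x,
#' train_labels, test_x, seed)` closure returning class-1 scores) lets
#' users plug them in.
#'
#' @param seed Integer seed (reserved for stochastic portfolio members;
#'   the reference methods are deterministic).
#' @param n_rounds Boosting rounds for the boosted pipelines.
#' @return A list of `pipeline_method` objects with unique `method_id`s.
#' @export
reference_portfolio <- function(seed = 1L, n_rounds = 40L) {
  boost_on <- function(prep) {
    force(prep)
    function(train_x, train_labels, test_x, seed) {
      lab <- train_labels != UNLABELED
      dat <- prep(train_x, test_x)
      model <- boost_fit(dat$train[lab, , drop = FALSE],
                         train_labels[lab], n_rounds = n_rounds)
      boost_predict(model, dat$test)
    }
  }
  list(
    new_pipeline_method("chained_boost",
      boost_on(function(tr, te) impute_chained(tr, te))),
    new_pipeline_method("indicator_lr",
      function(train_x, train_labels, test_x, seed) {
        lab <- train_labels != UNLABELED
        means <- train_col_means(train_x)
        has_na <- which(colSums(is.na(train_x)) > 0L)
        aug <- function(x) {
          filled <- fill_means(x, means)
          if (length(has_na)) cbind(filled, 1 * is.na(x[, has_na, drop = FALSE]))
          else filled
        }
        logit_fit_predict(aug(train_x)[lab, , drop = FALSE],
                          train_labels[lab], aug(test_x))
      }),
    new_pipeline_method("knn_boost",
      boost_on(function(tr, te) impute_knn(tr, te))),
    new_pipeline_method("mean_boost",
      boost_on(function(tr, te) {
        m <- train_col_means(tr)
        list(train = fill_means(tr, m), test = fill_means(te, m))
      })),
    new_pipeline_method("mean_lr",
      function(train_x, train_labels, test_x, seed) {
        lab <- train_labels != UNLABELED
        means <- train_col_means(train_x)
        logit_fit_predict(fill_means(train_x, means)[lab, , drop = FALSE],
                          train_labels[lab], fill_means(test_x, means))
      }),
    new_pipeline_method("native_boost",
      boost_on(function(tr, te) list(train = tr, test = te))))
}
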