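#' @title Filter feature scorers
#' @description Seven filter feature-selection methods sharing one contract:
#'   each returns a `feature_score` with a length-d vector of finite scores
#'   (higher = more relevant) and, for the methods whose natural output is an
#'   ordering (mRMR, LASSO, SVM-RFE), an explicit `selected_order`.
#'   [select_top_k()] consumes either. All scorers expect preprocessed
#'   (imputed, standardized) features and a binary 0/1 outcome containing
#'   both classes.
#' @name feature_scorers
NULL

new_feature_score <- function(scores, method, selected_order = NULL) {
  if (!all(is.finite(scores))) stop("internal: non-finite feature score")
  structure(list(scores = as.numeric(scores), method = method,
                 selected_order = selected_order),
            class = "feature_score")
}

check_xy <- function(x, y) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2) stop("outcome has a single class; scoring needs both")
  if (nrow(x) != length(y)) stop("feature matrix and outcome length differ")
  x
}

# Infinite statistics from zero within-class variance are capped one rank
# above the largest finite score, deterministically.
cap_infinite <- function(s) {
  bad <- !is.finite(s)
  if (any(bad)) {
    top <- if (any(!bad)) max(s[!bad]) else 0
    s[bad] <- top + 1
  }
  s
}

#' Absolute Welch t-statistic scorer
#'
#' Scores each feature by the absolute two-sample Welch t statistic between
#' the outcome classes (Welch rather than pooled for robustness to unequal
#' class variances). Features with zero variance in both classes score 0.
#'
#' @param x preprocessed N x d feature matrix.
#' @param y binary 0/1 outcome of length N.
#' @return a `feature_score`.
#' @export
score_t <- function(x, y) {
  x <- check_xy(x, y)
  x1 <- x[y == 1, , drop = FALSE]; x0 <- x[y == 0, , drop = FALSE]
  n1 <- nrow(x1); n0 <- nrow(x0)
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  v1 <- apply(x1, 2, stats::var); v0 <- apply(x0, 2, stats::var)
  se <- sqrt(v1 / n1 + v0 / n0)
  t <- abs(m1 - m0) / se
  t[se == 0 & m1 == m0] <- 0            # flat in both classes
  new_feature_score(cap_infinite(t), "t_score")
}

#' One-way ANOVA F scorer
#'
#' Scores each feature by the one-way analysis-of-variance F statistic across
#' the two outcome classes (equal to the squared pooled-variance t statistic
#' for two groups). Degenerate features with no within-class variance get the
#' capped maximal score; all-constant features score 0.
#'
#' @inheritParams score_t
#' @return a `feature_score`.
#' @export
score_f <- function(x, y) {
  x <- check_xy(x, y)
  n <- nrow(x); k <- 2
  x1 <- x[y == 1, , drop = FALSE]; x0 <- x[y == 0, , drop = FALSE]
  n1 <- nrow(x1); n0 <- nrow(x0)
  m1 <- colMeans(x1); m0 <- colMeans(x0); m <- colMeans(x)
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ssw <- (n1 - 1) * apply(x1, 2, stats::var) +
         (n0 - 1) * apply(x0, 2, stats::var)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssb == 0 & ssw == 0] <- 0           # all-constant feature
  new_feature_score(cap_infinite(f), "f_score")
}

#' Mutual information maximization (MIM) scorer
#'
#' Scores each feature by the plug-in empirical mutual information (natural
#' logarithm, nats) between the feature discretized into `n_bins`
#' equal-frequency bins and the outcome. Equal-frequency binning makes the
#' score invariant to strictly monotone transforms of a feature.
#'
#' @inheritParams score_t
#' @param n_bins number of equal-frequency bins (>= 2); default 10.
#' @return a `feature_score`.
#' @export
score_mim <- function(x, y, n_bins = 10L) {
  x <- check_xy(x, y)
  if (n_bins < 2) stop("n_bins must be >= 2")
  scores <- apply(x, 2, function(col) {
    brk <- unique(stats::quantile(col, probs = seq(0, 1, length.out = n_bins + 1),
                                  names = FALSE, type = 7))
    if (length(brk) < 2) return(0)      # constant feature
    bins <- cut(col, breaks = brk, include.lowest = TRUE, labels = FALSE)
    mutual_information(bins, y)
  })
  new_feature_score(scores, "mim")
}

# Plug-in MI of two discrete vectors, in nats.
mutual_information <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  pe <- outer(pa, pb)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / pe[nz]))
}

#' ReliefF scorer
#'
#' Standard ReliefF feature weighting: for each anchor sample, the
#' `n_neighbors` nearest hits (same class) and misses (other class) are found
#' under Manhattan distance on all features; each feature's weight
#' accumulates the normalized miss-difference minus hit-difference, averaged
#' over anchors and neighbors. By default every sample acts as an anchor,
#' which makes the weights deterministic; `n_anchors` smaller than N samples
#' anchors at random under `seed`.
#'
#' @inheritParams score_t
#' @param n_neighbors hits/misses per anchor (default 10); every class must
#'   have more than `n_neighbors` members.
#' @param n_anchors number of anchor samples, or `NULL` for all.
#' @param seed seed for anchor subsampling (unused when all samples anchor).
#' @return a `feature_score`.
#' @export
score_relieff <- function(x, y, n_neighbors = 10L, n_anchors = NULL, seed = 1L) {
  x <- check_xy(x, y)
  n <- nrow(x); d <- ncol(x)
  if (min(table(y)) <= n_neighbors)
    stop(sprintf("each class needs > %d members for %d neighbors",
                 n_neighbors, n_neighbors))
  rng <- apply(x, 2, function(col) diff(range(col)))
  ok <- rng > 0                          # constant features keep weight 0
  anchors <- if (is.null(n_anchors) || n_anchors >= n) seq_len(n) else
    with_seed(seed, sample(n, n_anchors))
  w <- numeric(d)
  xn <- sweep(x[, ok, drop = FALSE], 2, rng[ok], "/")  # range-normalized once
  for (i in anchors) {
    diffs <- abs(sweep(xn, 2, xn[i, ], "-"))           # n x d_ok
    dist <- rowSums(diffs)
    dist[i] <- Inf
    hits <- which(y == y[i]); hits <- hits[hits != i]
    misses <- which(y != y[i])
    nh <- hits[order(dist[hits])[seq_len(n_neighbors)]]
    nm <- misses[order(dist[misses])[seq_len(n_neighbors)]]
    w[ok] <- w[ok] + colSums(diffs[nm, , drop = FALSE]) -
                     colSums(diffs[nh, , drop = FALSE])
  }
  w <- w / (length(anchors) * n_neighbors)
  new_feature_score(w, "relieff")
}

#' Greedy minimum-redundancy maximum-relevance (mRMR) scorer
#'
#' Greedy forward selection with the difference criterion: relevance of a
#' feature is its MIM score against the outcome; redundancy against the
#' already-selected set is the mean absolute Pearson correlation. The first
#' pick maximizes relevance; each later pick maximizes relevance minus
#' redundancy. `selected_order` holds the `k` picks; the full score vector
#' ranks the picks first (in order), then the remaining features by
#' relevance.
#'
#' @inheritParams score_t
#' @param k number of greedy picks, `1 <= k <= d`.
#' @param n_bins bins for the MIM relevance term.
#' @return a `feature_score` with `selected_order`.
#' @export
score_mrmr <- function(x, y, k, n_bins = 10L) {
  x <- check_xy(x, y)
  d <- ncol(x)
  if (k < 1 || k > d) stop("k must satisfy 1 <= k <= d")
  relevance <- score_mim(x, y, n_bins = n_bins)$scores
  selected <- integer(0)
  candidates <- seq_len(d)
  mean_abs_cor <- numeric(d)             # running mean |cor| with selected
  for (step in seq_len(k)) {
    crit <- if (step == 1) relevance[candidates] else
      relevance[candidates] - mean_abs_cor[candidates]
    pick <- candidates[which.max(crit)]  # which.max ties -> lowest index
    selected <- c(selected, pick)
    candidates <- setdiff(candidates, pick)
    if (length(candidates) && step < k) {
      r <- abs(suppressWarnings(stats::cor(x[, candidates, drop = FALSE],
                                           x[, pick])))
      r[is.na(r)] <- 0                   # constant features: no redundancy
      mean_abs_cor[candidates] <-
        (mean_abs_cor[candidates] * (step - 1) + as.numeric(r)) / step
    }
  }
  rest <- setdiff(seq_len(d), selected)
  full_order <- c(selected, rest[order(-relevance[rest], rest)])
  scores <- numeric(d); scores[full_order] <- d - seq_len(d) + 1
  new_feature_score(scores, "mrmr", selected_order = selected)
}

#' LASSO entry-order scorer
#'
#' Fits an L1-penalized logistic regression along a decreasing geometric grid
#' of penalties, from the smallest penalty that zeroes every coefficient down
#' by a factor of 1e-3 over `n_lambda` steps, and ranks features by the
#' penalty at which they first enter the active set (earlier entry = higher
#' score). Ties are broken by larger absolute coefficient at the final
#' penalty; features that never enter rank last, ordered by absolute final
#' coefficient then index.
#'
#' @inheritParams score_t
#' @param n_lambda number of penalty steps (>= 50).
#' @return a `feature_score` with `selected_order` (the full entry ranking).
#' @export
score_lasso <- function(x, y, n_lambda = 60L) {
  x <- check_xy(x, y)
  d <- ncol(x)
  if (d < 2) return(new_feature_score(rep(1, d), "lasso", selected_order = seq_len(d)))
  fit0 <- glmnet::glmnet(x, factor(y), family = "binomial", alpha = 1,
                         standardize = FALSE, nlambda = 5)
  lambda_max <- fit0$lambda[1]
  lambdas <- lambda_max * 10^seq(0, -3, length.out = max(50L, n_lambda))
  fit <- tryCatch(
    glmnet::glmnet(x, factor(y), family = "binomial", alpha = 1,
                   standardize = FALSE, lambda = lambdas),
    error = function(e) stop(sprintf(
      "LASSO path failed over %d penalty steps from %.3g: %s",
      length(lambdas), lambda_max, conditionMessage(e))))
  beta <- as.matrix(fit$beta)            # d x n_lambda actually fitted
  entry <- apply(beta != 0, 1, function(r) if (any(r)) which(r)[1] else Inf)
  final <- abs(beta[, ncol(beta)])
  full_order <- order(entry, -final, seq_len(d))
  scores <- numeric(d); scores[full_order] <- d - seq_len(d) + 1
  new_feature_score(scores, "lasso", selected_order = full_order)
}

#' SVM recursive feature elimination (SVM-RFE) scorer
#'
#' Recursive elimination with a linear soft-margin SVM (cost C = 1): train on
#' the surviving features, rank them by squared weight, drop the lower-ranked
#' half while more than 64 features remain, then one feature per iteration.
#' The elimination order reversed gives the ranking (last survivor = best).
#'
#' @inheritParams score_t
#' @return a `feature_score` with `selected_order` (best feature first).
#' @export
score_svm_rfe <- function(x, y) {
  x <- check_xy(x, y)
  d <- ncol(x)
  yf <- factor(y, levels = c(0, 1))
  surviving <- seq_len(d)
  eliminated <- integer(0)
  while (length(surviving) > 1) {
    fit <- e1071::svm(x[, surviving, drop = FALSE], yf, kernel = "linear",
                      cost = 1, scale = FALSE)
    w <- crossprod(fit$coefs, fit$SV)    # 1 x |surviving|
    rank_val <- as.numeric(w)^2
    n_drop <- if (length(surviving) > 64) floor(length(surviving) / 2) else 1L
    drop_local <- order(rank_val, seq_along(surviving))[seq_len(n_drop)]
    # worst dropped first within a batch so the reversed order is a ranking
    eliminated <- c(eliminated, surviving[drop_local])
    surviving <- surviving[-drop_local]
  }
  full_order <- c(surviving, rev(eliminated))
  scores <- numeric(d); scores[full_order] <- d - seq_len(d) + 1
  new_feature_score(scores, "svm_rfe", selected_order = full_order)
}

#' Score features by a named method
#'
#' Dispatch wrapper used by the cross-validation engine; `method` is one of
#' `"t_score"`, `"f_score"`, `"mim"`, `"relieff"`, `"mrmr"`, `"lasso"`,
#' `"svm_rfe"`. `k` is forwarded to mRMR (its greedy depth); the other
#' methods score all features regardless of `k`.
#'
#' @inheritParams score_t
#' @param method scorer name.
#' @param k intended selection size (used by mRMR).
#' @param ... further arguments passed to the scorer.
#' @return a `feature_score`.
#' @export
score_features <- function(x, y, method, k = ncol(as.matrix(x)), ...) {
  k <- min(k, ncol(as.matrix(x)))
  switch(method,
    t_score = score_t(x, y),
    f_score = score_f(x, y),
    mim = score_mim(x, y, ...),
    relieff = score_relieff(x, y, ...),
    mrmr = score_mrmr(x, y, k = max(k, 1L), ...),
    lasso = score_lasso(x, y, ...),
    svm_rfe = score_svm_rfe(x, y),
    stop(sprintf("unknown feature-selection method '%s'", method))
  )
}

#' Methods and selection sizes of the standard grid
#'
#' The seven filter methods and the selection-size grid
#' k in {1, 2, 4, 8, 16, 32} used throughout the bias experiments.
#' @return a list with `methods` and `k_grid`.
#' @export
selector_grid <- function() {
  list(methods = c("lasso", "t_score", "f_score", "mrmr", "relieff", "mim",
                   "svm_rfe"),
       k_grid = c(1L, 2L, 4L, 8L, 16L, 32L))
}

#' Select the top-k features from a score
#'
#' Takes the `k` highest-scoring features, or the first `k` of
#' `selected_order` when the scorer produced an explicit ranking. Ties break
#' deterministically by ascending feature index; `k` larger than d is capped
#' with a warning. Indices are returned sorted ascending (a feature set).
#'
#' @param score a `feature_score`.
#' @param k number of features to keep (>= 1).
#' @return sorted integer vector of selected feature indices.
#' @export
select_top_k <- function(score, k) {
  stopifnot(inherits(score, "feature_score"), k >= 1)
  d <- length(score$scores)
  if (k > d) {
    warning(sprintf("k = %d exceeds feature count %d; capped", k, d))
    k <- d
  }
  idx <- if (!is.null(score$selected_order)) {
    if (length(score$selected_order) < k)
      stop(sprintf("selected_order holds %d picks but k = %d requested",
                   length(score$selected_order), k))
    score$selected_order[seq_len(k)]
  } else {
    order(-score$scores, seq_len(d))[seq_len(k)]
  }
  sort(idx)
}
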