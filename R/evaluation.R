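#' Area under the ROC curve (micro-averaged)
#'
#' Computed on pooled out-of-fold predictions by the rank (Mann-Whitney)
#' formula: the probability that a random positive outscores a random
#' negative, with ties counted 1/2.
#'
#' @param preds a `pooled_predictions`, or a numeric probability vector (then
#'   supply `labels`).
#' @param labels 0/1 labels when `preds` is a bare vector.
#' @return AUC-ROC in `[0, 1]`.
#' @export
auc_roc <- function(preds, labels = NULL) {
  p <- resolve_preds(preds, labels)
  n1 <- sum(p$labels == 1L); n0 <- length(p$labels) - n1
  if (n1 == 0 || n0 == 0) stop("AUC-ROC needs both classes in the labels")
  r <- rank(p$probs)                     # average ranks handle ties at 1/2
  (sum(r[p$labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average-precision rule over descending unique thresholds:
#' `sum_i (R_i - R_{i-1}) * P_i`, which avoids the optimistic linear
#' interpolation of the trapezoid rule. Also reported by the pipeline under
#' its radiomics alias "AUC-F1".
#'
#' @inheritParams auc_roc
#' @return average precision in `[0, 1]`.
#' @export
auc_pr <- function(preds, labels = NULL) {
  p <- resolve_preds(preds, labels)
  n_pos <- sum(p$labels == 1L)
  if (n_pos == 0) stop("AUC-PR needs at least one positive label")
  ord <- order(p$probs, decreasing = TRUE)
  probs <- p$probs[ord]; y <- p$labels[ord]
  tp <- cumsum(y == 1L); fp <- cumsum(y == 0L)
  last <- c(probs[-1] != probs[-length(probs)], TRUE)  # ends of tie groups
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Confusion-matrix metrics at a probability threshold
#'
#' Predicted class is 1 iff probability >= `threshold` (default 0.5).
#' Precision over an empty positive-prediction set is defined as 0.
#'
#' @inheritParams auc_roc
#' @param threshold decision threshold on the positive-class probability.
#' @return named list: accuracy, sensitivity, specificity, precision, recall
#'   (recall = sensitivity by definition).
#' @export
threshold_metrics <- function(preds, labels = NULL, threshold = 0.5) {
  p <- resolve_preds(preds, labels)
  yhat <- as.integer(p$probs >= threshold)
  y <- p$labels
  tp <- sum(yhat == 1L & y == 1L); tn <- sum(yhat == 0L & y == 0L)
  fp <- sum(yhat == 1L & y == 0L); fn <- sum(yhat == 0L & y == 1L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(accuracy = (tp + tn) / length(y),
       sensitivity = sens,
       specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = sens)
}

resolve_preds <- function(preds, labels) {
  if (inherits(preds, "pooled_predictions"))
    list(probs = preds$probs, labels = preds$labels)
  else
    list(probs = as.numeric(preds), labels = as.integer(labels))
}

#' Evaluate pooled predictions on all metrics
#'
#' @param preds a `pooled_predictions`.
#' @return an `evaluation_result`: auc_roc, auc_pr, accuracy, sensitivity,
#'   specificity, precision, recall, plus the prediction provenance.
#' @export
evaluate_predictions <- function(preds) {
  tm <- threshold_metrics(preds)
  structure(c(list(auc_roc = auc_roc(preds), auc_pr = auc_pr(preds)), tm,
              list(provenance = preds$provenance, scheme = preds$scheme)),
            class = "evaluation_result")
}

#' Pick the best result by a metric
#'
#' Argmax over a list of `evaluation_result`s; exact ties are broken by the
#' stable enumeration order of the grid (the earliest entry wins).
#'
#' @param results non-empty list of `evaluation_result`s.
#' @param metric metric name (default `"auc_roc"`).
#' @return the index of the best result.
#' @export
select_best <- function(results, metric = "auc_roc") {
  if (!length(results)) stop("select_best needs a non-empty result list")
  vals <- vapply(results, function(r) r[[metric]], numeric(1))
  which.max(vals)                        # which.max tie -> earliest
}

#' Compare the best models of the two schemes
#'
#' Selects the highest-AUC-ROC model within each scheme, then reports the
#' per-metric difference A - B (the optimism bias attributable to leaky
#' feature selection) for AUC-ROC, AUC-PR and accuracy, together with paired
#' bootstrap p-values for the null of zero difference.
#'
#' @param runs_a,runs_b lists of `pooled_predictions` from scheme A and B on
#'   the same dataset (same samples).
#' @param n_boot bootstrap repeats (default 2000).
#' @param seed bootstrap seed.
#' @return a `scheme_comparison`: `best_a`, `best_b` (each with provenance and
#'   metrics), `delta`, and `p_values`.
#' @export
compare_schemes <- function(runs_a, runs_b, n_boot = 2000L, seed = 1L) {
  if (!length(runs_a) || !length(runs_b))
    stop("both schemes need at least one run")
  if (length(unique(vapply(c(runs_a, runs_b), function(r) length(r$labels),
                           integer(1)))) != 1)
    stop("scheme A and B runs must cover the same dataset")
  res_a <- lapply(runs_a, evaluate_predictions)
  res_b <- lapply(runs_b, evaluate_predictions)
  ia <- select_best(res_a); ib <- select_best(res_b)
  metrics <- c("auc_roc", "auc_pr", "accuracy")
  delta <- vapply(metrics, function(m) res_a[[ia]][[m]] - res_b[[ib]][[m]],
                  numeric(1))
  p_values <- bootstrap_delta_test(runs_a[[ia]], runs_b[[ib]],
                                   n_boot = n_boot, seed = seed)
  structure(list(best_a = res_a[[ia]], best_b = res_b[[ib]],
                 delta = delta, p_values = p_values),
            class = "scheme_comparison")
}

metric_fun <- function(metric) {
  switch(metric,
    auc_roc = function(p, y) auc_roc(p, y),
    auc_pr = function(p, y) auc_pr(p, y),
    accuracy = function(p, y) threshold_metrics(p, y)$accuracy,
    stop(sprintf("unknown metric '%s'", metric)))
}

#' Paired bootstrap test for a metric difference
#'
#' Draws N sample indices with replacement, recomputes the metric on both
#' prediction vectors restricted to the draw, and forms the difference
#' `delta_b = metric_A - metric_B`. The two-sided p-value is
#' `2 * min(#{delta_b <= 0}, #{delta_b >= 0}) / n_boot`, clipped to
#' `[2/n_boot, 1]`. Resamples containing a single outcome class are redrawn.
#' Identical prediction vectors give p = 1 exactly.
#'
#' @param preds_a,preds_b `pooled_predictions` over the same samples in the
#'   same order.
#' @param metrics metric names to test.
#' @param n_boot bootstrap repeats (default 2000).
#' @param seed integer seed.
#' @return named numeric vector of p-values.
#' @export
bootstrap_delta_test <- function(preds_a, preds_b,
                                 metrics = c("auc_roc", "auc_pr", "accuracy"),
                                 n_boot = 2000L, seed = 1L) {
  if (!identical(preds_a$labels, preds_b$labels))
    stop("paired bootstrap needs identical samples (labels differ)")
  n <- length(preds_a$labels)
  y <- preds_a$labels
  pa <- preds_a$probs; pb <- preds_b$probs
  funs <- lapply(metrics, metric_fun)
  deltas <- matrix(NA_real_, n_boot, length(metrics))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2) break
      }
      yb <- y[idx]
      for (m in seq_along(funs))
        deltas[b, m] <- funs[[m]](pa[idx], yb) - funs[[m]](pb[idx], yb)
    }
  })
  p <- vapply(seq_along(metrics), function(m) {
    lo <- sum(deltas[, m] <= 0); hi <- sum(deltas[, m] >= 0)
    min(1, max(2 / n_boot, 2 * min(lo, hi) / n_boot))
  }, numeric(1))
  stats::setNames(p, metrics)
}

#' Per-(selector, classifier) mean bias matrix
#'
#' For each dataset and each selector x classifier combination, takes the
#' best-AUC-ROC model per scheme within that combination and forms the
#' difference A - B; cells report the mean and range over datasets. This
#' mimics studies that fix one selector and one classifier without a wider
#' search.
#'
#' @param results data frame with columns `dataset`, `scheme`, `selector`,
#'   `classifier`, `auc_roc` (one row per fitted grid cell), e.g. the
#'   `results` element of [run_experiment()].
#' @return a data frame with one row per combination: `selector`,
#'   `classifier`, `mean_bias`, `min_bias`, `max_bias`, `n_datasets`.
#' @export
combination_bias <- function(results) {
  need <- c("dataset", "scheme", "selector", "classifier", "auc_roc")
  if (!all(need %in% names(results)))
    stop(sprintf("results must have columns: %s", paste(need, collapse = ", ")))
  combos <- unique(results[, c("selector", "classifier")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- results[results$selector == combos$selector[i] &
                   results$classifier == combos$classifier[i], ]
    diffs <- vapply(unique(sub$dataset), function(ds) {
      a <- sub$auc_roc[sub$dataset == ds & sub$scheme == "A"]
      b <- sub$auc_roc[sub$dataset == ds & sub$scheme == "B"]
      if (!length(a) || !length(b)) return(NA_real_)
      max(a) - max(b)
    }, numeric(1))
    diffs <- diffs[!is.na(diffs)]
    data.frame(selector = combos$selector[i], classifier = combos$classifier[i],
               mean_bias = if (length(diffs)) mean(diffs) else NA_real_,
               min_bias = if (length(diffs)) min(diffs) else NA_real_,
               max_bias = if (length(diffs)) max(diffs) else NA_real_,
               n_datasets = length(diffs))
  })
  do.call(rbind, rows)
}

#' Regress leakage bias on dataset dimensionality
#'
#' Ordinary least squares of bias on samples-per-feature (N/d) over datasets,
#' with the Pearson correlation and its two-sided p-value (t with n-2
#' degrees of freedom). A negative correlation means datasets with fewer
#' samples per feature suffer more leakage optimism.
#'
#' @param points data frame with columns `samples_per_feature` and `bias`
#'   (>= 3 rows, non-constant x).
#' @return a `bias_regression_result`: `points`, `pearson_r`, `slope`,
#'   `intercept`, `p_value`.
#' @export
bias_vs_dimensionality <- function(points) {
  if (nrow(points) < 3) stop("regression needs at least 3 points")
  x <- points$samples_per_feature; y <- points$bias
  if (stats::sd(x) == 0) stop("samples_per_feature is constant; cannot regress")
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  structure(list(points = points,
                 pearson_r = unname(ct$estimate),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 p_value = ct$p.value),
            class = "bias_regression_result")
}
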