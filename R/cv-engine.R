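#' Stratified k-fold assignment
#'
#' Splits samples into `K` folds of near-equal size while keeping the class
#' balance of every fold close to the overall balance: within each class the
#' samples are shuffled and dealt out so per-fold class counts differ from
#' exact proportionality by at most one, and the per-class remainders are
#' placed on the currently least-loaded folds so total fold sizes also differ
#' by at most one. Deterministic given `seed`.
#'
#' @param y length-N 0/1 outcome; every class must have at least `K` members.
#' @param K number of folds (default 10).
#' @param seed integer seed.
#' @return a `fold_assignment`: list with `fold_of` (length-N integers in
#'   `1..K`), `K` and `seed`.
#' @export
stratified_kfold <- function(y, K = 10L, seed = 1L) {
  y <- as.integer(y)
  n <- length(y)
  tab <- table(y)
  small <- names(tab)[tab < K]
  if (length(small))
    stop(sprintf("class %s has only %d member(s); %d folds need >= %d",
                 small[1], tab[small[1]], K, K))
  fold_of <- integer(n)
  load <- integer(K)
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- sample(which(y == cls))
      n_c <- length(idx)
      base <- n_c %/% K
      rem <- n_c %% K
      counts <- rep(base, K)
      if (rem > 0) {
        extra <- order(load, seq_len(K))[seq_len(rem)]
        counts[extra] <- counts[extra] + 1L
      }
      fold_of[idx] <- rep(seq_len(K), counts)
      load <- load + counts
    }
  })
  structure(list(fold_of = fold_of, K = as.integer(K), seed = as.integer(seed)),
            class = "fold_assignment")
}

new_pooled_predictions <- function(probs, labels, fold_of, scheme,
                                   provenance = list(),
                                   fold_features = NULL) {
  stopifnot(length(probs) == length(labels),
            all(probs >= 0 & probs <= 1))
  structure(list(probs = as.numeric(probs), labels = as.integer(labels),
                 fold_of = fold_of, scheme = scheme, provenance = provenance,
                 fold_features = fold_features),
            class = "pooled_predictions")
}

run_scheme <- function(dataset, selector, clf, folds, scheme,
                       scorer_hook = NULL) {
  stopifnot(inherits(dataset, "radiomics_dataset"),
            inherits(folds, "fold_assignment"),
            scheme %in% c("A", "B"))
  x <- dataset$features
  y <- dataset$outcome
  n <- nrow(x); d <- ncol(x)
  k <- min(selector$k, d)
  score_once <- function(xs, ys) {
    if (!is.null(scorer_hook)) scorer_hook()
    score_features(xs, ys, method = selector$method, k = k)
  }
  if (scheme == "A") {
    # The deliberate leak: features scored once on ALL samples and labels.
    global_sel <- select_top_k(score_once(x, y), k)
  }
  probs <- rep(NA_real_, n)
  fold_features <- vector("list", folds$K)
  for (f in seq_len(folds$K)) {
    test <- folds$fold_of == f
    sel <- if (scheme == "A") global_sel else
      select_top_k(score_once(x[!test, , drop = FALSE], y[!test]), k)
    fold_features[[f]] <- sel
    cfg <- clf
    cfg$seed <- derive_seed(folds$seed, f, config_id(clf))
    fm <- fit_classifier(cfg, x[!test, sel, drop = FALSE], y[!test])
    probs[test] <- predict_proba(fm, x[test, sel, drop = FALSE])
  }
  new_pooled_predictions(probs, y, folds, scheme,
    provenance = list(selector = selector, classifier = config_id(clf),
                      classifier_config = clf),
    fold_features = fold_features)
}

#' Run the leaky training scheme (feature selection before CV)
#'
#' Scheme A: the feature scorer runs once on all N samples, outcome labels
#' included — so every held-out fold has already leaked into the selection —
#' and the same top-k feature set is then used in every fold: the classifier
#' is trained on the K-1 training folds restricted to those features and
#' predicts probabilities on the held-out fold. Out-of-fold predictions are
#' pooled into one vector (micro-averaging substrate).
#'
#' @param dataset a preprocessed `radiomics_dataset`.
#' @param selector list with `method` (see [score_features()]) and `k`.
#' @param clf a `classifier_config`.
#' @param folds a [stratified_kfold()] assignment (share one assignment
#'   between the two schemes so their difference isolates the leak).
#' @param scorer_hook optional zero-argument function called once per scorer
#'   invocation (instrumentation for tests).
#' @return a `pooled_predictions` with scheme `"A"`.
#' @export
run_scheme_a <- function(dataset, selector, clf, folds, scorer_hook = NULL) {
  run_scheme(dataset, selector, clf, folds, "A", scorer_hook)
}

#' Run the nested training scheme (feature selection inside CV)
#'
#' Scheme B: within each fold, the feature scorer sees only the K-1 training
#' folds; the held-out fold contributes nothing to selection, so the pooled
#' out-of-fold predictions are not inflated by selection leakage. Each fold
#' may select a different feature set; the per-fold sets are recorded in the
#' result's `fold_features`.
#'
#' @inheritParams run_scheme_a
#' @return a `pooled_predictions` with scheme `"B"`.
#' @export
run_scheme_b <- function(dataset, selector, clf, folds, scorer_hook = NULL) {
  run_scheme(dataset, selector, clf, folds, "B", scorer_hook)
}
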