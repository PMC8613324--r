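# Small fixture builders shared across test files. Everything is generated
# in code under fixed seeds; nothing is read from disk.

# A preprocessed null dataset (no feature-outcome association).
null_dataset <- function(n = 100, d = 1000, seed = 1, prevalence = 0.5) {
  preprocess(generate_dataset(
    dataset_spec(n, d, prevalence = prevalence, seed = seed)))$dataset
}

# A preprocessed dataset with planted signal in the first `n_informative`
# columns.
signal_dataset <- function(n = 200, d = 200, n_informative = 8,
                           effect_size = 1, seed = 1) {
  preprocess(generate_dataset(
    dataset_spec(n, d, prevalence = 0.5, n_informative = n_informative,
                 effect_size = effect_size, seed = seed)))$dataset
}

# Brute-force all-pairs AUC oracle: fraction of (positive, negative) pairs
# where the positive outscores the negative, ties counted 1/2. Independent
# of the rank-formula implementation.
auc_bruteforce <- function(probs, labels) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Pooled-variance two-sample t statistic (oracle for the F = t^2 identity).
pooled_t <- function(x, y) {
  x1 <- x[y == 1]; x0 <- x[y == 0]
  n1 <- length(x1); n0 <- length(x0)
  sp2 <- ((n1 - 1) * var(x1) + (n0 - 1) * var(x0)) / (n1 + n0 - 2)
  (mean(x1) - mean(x0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
}

make_preds <- function(probs, labels, scheme = "A") {
  foldleak:::new_pooled_predictions(probs, labels,
    fold_of = NULL, scheme = scheme)
}
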