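#' Specification of a synthetic radiomics-like dataset
#'
#' Describes a tabular classification dataset of `n_samples` rows by
#' `n_features` numeric columns with a binary outcome. Features are drawn in
#' equicorrelated blocks (a shared latent factor per block), optionally with
#' the first `n_informative` columns shifted between classes by `effect_size`
#' standard deviations, and optionally with a sub-1% rate of missing cells —
#' the regime typical of published radiomics feature tables, where features
#' are highly redundant, samples are scarce (often fewer samples than
#' features) and missingness from numerical failures is rare.
#'
#' @param n_samples positive integer, number of samples N.
#' @param n_features positive integer, number of features d.
#' @param prevalence fraction of positive outcomes, in (0, 1).
#' @param n_informative number of signal-carrying features (the first
#'   `n_informative` columns), `0 <= n_informative <= n_features`. Zero gives
#'   a null dataset with no feature-outcome association.
#' @param effect_size standardized mean shift of informative features in the
#'   positive class, non-negative.
#' @param block_size features per correlated block (1 = independent features).
#' @param within_block_correlation pairwise correlation inside a block, in
#'   `[0, 1)`.
#' @param missing_rate per-cell missingness probability, in `[0, 0.01]`.
#' @param seed integer RNG seed; the dataset is a deterministic function of
#'   the spec including the seed.
#' @return an object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_samples, n_features, prevalence = 0.5,
                         n_informative = 0, effect_size = 0,
                         block_size = 1, within_block_correlation = 0,
                         missing_rate = 0, seed = 1L) {
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 2 ||
      n_samples != round(n_samples))
    stop_field("n_samples", "must be an integer >= 2")
  if (!is.numeric(n_features) || length(n_features) != 1 || n_features < 1 ||
      n_features != round(n_features))
    stop_field("n_features", "must be a positive integer")
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop_field("prevalence", "must lie strictly inside (0, 1)")
  if (n_informative < 0 || n_informative > n_features)
    stop_field("n_informative", "must satisfy 0 <= n_informative <= n_features")
  if (effect_size < 0) stop_field("effect_size", "must be non-negative")
  if (block_size < 1 || block_size > n_features)
    stop_field("block_size", "must satisfy 1 <= block_size <= n_features")
  if (within_block_correlation < 0 || within_block_correlation >= 1)
    stop_field("within_block_correlation", "must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate > 0.01)
    stop_field("missing_rate", "must lie in [0, 0.01] (sub-1% regime)")
  structure(list(
    n_samples = as.integer(n_samples), n_features = as.integer(n_features),
    prevalence = prevalence, n_informative = as.integer(n_informative),
    effect_size = effect_size, block_size = as.integer(block_size),
    within_block_correlation = within_block_correlation,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "dataset_spec")
}

new_radiomics_dataset <- function(features, outcome, feature_names = NULL,
                                  sample_ids = NULL, informative = integer(0)) {
  features <- as.matrix(features)
  n <- nrow(features); d <- ncol(features)
  feature_names <- feature_names %||% colnames(features) %||%
    sprintf("feat_%04d", seq_len(d))
  sample_ids <- sample_ids %||% rownames(features) %||%
    sprintf("sample_%04d", seq_len(n))
  if (anyDuplicated(feature_names)) stop("feature names must be unique")
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (length(outcome) != n) stop("outcome length must match sample count")
  if (!all(outcome %in% c(0L, 1L))) stop("outcome must be coded {0, 1}")
  dimnames(features) <- list(sample_ids, feature_names)
  structure(list(features = features, outcome = as.integer(outcome),
                 feature_names = feature_names, sample_ids = sample_ids,
                 informative = as.integer(informative)),
            class = "radiomics_dataset")
}

#' @export
print.radiomics_dataset <- function(x, ...) {
  cat(sprintf(
    "radiomics_dataset: %d samples x %d features | prevalence %.3f | %d informative | %d missing cells\n",
    nrow(x$features), ncol(x$features), mean(x$outcome),
    length(x$informative), sum(is.na(x$features))))
  invisible(x)
}

#' Number of samples per feature
#'
#' The dimensionality ratio N/d; values below 1 mean the dataset is
#' high-dimensional (fewer samples than features).
#'
#' @param dataset a `radiomics_dataset`.
#' @return a positive real.
#' @export
samples_per_feature <- function(dataset) {
  nrow(dataset$features) / ncol(dataset$features)
}

#' Generate a synthetic radiomics-like dataset
#'
#' Draws features block-wise from a joint normal with unit variances, zero
#' means, and the spec's pairwise within-block correlation (via a shared
#' latent factor per block: `x = sqrt(rho) z_block + sqrt(1 - rho) eps`).
#' The outcome has exactly `round(N * prevalence)` positives (exact-count
#' assignment, then a seeded shuffle) so class counts are reproducible across
#' fold-splitting edge cases. Each of the first `n_informative` features gets
#' its class-conditional mean raised by `effect_size` (in standard-deviation
#' units) in the positive class. Missing cells, if requested, are injected by
#' [inject_missing()] with a seed derived from the spec's.
#'
#' @param spec a [dataset_spec()].
#' @return a `radiomics_dataset`; the informative column indices are recorded
#'   in its `informative` field (test scaffolding, not visible to any scorer).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  n <- spec$n_samples; d <- spec$n_features
  rho <- spec$within_block_correlation
  n_pos <- round(n * spec$prevalence)
  if (n_pos < 1 || n_pos > n - 1)
    stop_field("prevalence", "must leave at least one sample in each class")
  out <- with_seed(spec$seed, {
    y <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
    block_of <- rep(seq_len(ceiling(d / spec$block_size)),
                    each = spec$block_size, length.out = d)
    eps <- matrix(stats::rnorm(n * d), n, d)
    if (rho > 0) {
      z <- matrix(stats::rnorm(n * max(block_of)), n, max(block_of))
      x <- sqrt(rho) * z[, block_of, drop = FALSE] + sqrt(1 - rho) * eps
    } else {
      x <- eps
    }
    if (spec$n_informative > 0) {
      idx <- seq_len(spec$n_informative)
      x[y == 1L, idx] <- x[y == 1L, idx, drop = FALSE] + spec$effect_size
    }
    list(x = x, y = y)
  })
  ds <- new_radiomics_dataset(out$x, out$y,
                              informative = seq_len(spec$n_informative))
  if (spec$missing_rate > 0)
    ds <- inject_missing(ds, spec$missing_rate,
                         seed = derive_seed(spec$seed, "missing"))
  ds
}

#' Inject missing cells at a sub-1% rate
#'
#' Replaces each feature cell independently by `NA` with probability
#' `missing_rate`, never touching the outcome and never allowing a column to
#' become entirely missing (the first masked cell of such a column is
#' restored). Rates above 1% are rejected: the regime emulated here is the
#' rare numerical-failure missingness of radiomics feature extraction.
#'
#' @param dataset a `radiomics_dataset`.
#' @param missing_rate per-cell probability in `[0, 0.01]`.
#' @param seed integer seed.
#' @return the dataset with `NA`s in its feature matrix.
#' @export
inject_missing <- function(dataset, missing_rate, seed = 1L) {
  stopifnot(inherits(dataset, "radiomics_dataset"))
  if (missing_rate < 0 || missing_rate > 0.01)
    stop_field("missing_rate", "must lie in [0, 0.01] (sub-1% regime)")
  if (nrow(dataset$features) < 2) stop("dataset must have >= 2 samples")
  if (missing_rate == 0) return(dataset)
  x <- dataset$features
  mask <- with_seed(seed, matrix(stats::runif(length(x)) < missing_rate,
                                 nrow(x), ncol(x)))
  for (j in which(colSums(!mask) == 0)) mask[1L, j] <- FALSE
  x[mask] <- NA_real_
  dataset$features <- x
  dataset
}

#' Write a dataset to CSV
#'
#' One header row; a `SampleID` column, the feature columns, and the outcome
#' column (default name `"Target"`, values 0/1). Missing cells are written as
#' empty fields. UTF-8, '.' decimal, comma separator; numerics carry 15
#' significant digits so a write/read round trip reproduces them.
#'
#' @param dataset a `radiomics_dataset`.
#' @param path output file path.
#' @param outcome_col name of the outcome column.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, outcome_col = "Target") {
  stopifnot(inherits(dataset, "radiomics_dataset"))
  df <- data.frame(SampleID = dataset$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  feat <- as.data.frame(dataset$features)
  for (j in seq_along(feat))
    feat[[j]] <- ifelse(is.na(feat[[j]]), "",
                        format(feat[[j]], digits = 15, trim = TRUE,
                               scientific = TRUE))
  df <- cbind(df, feat)
  df[[outcome_col]] <- dataset$outcome
  utf8 <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(utf8))
  utils::write.table(df, utf8, sep = ",", dec = ".", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read a dataset from CSV
#'
#' Expects one header row, numeric feature columns, one binary outcome column
#' and (optionally) a `SampleID` column; empty cells become missing values.
#' Outcomes must be coded 0/1 unless `remap_outcome = TRUE`, in which case
#' exactly two observed values are mapped to 0/1 by sorted order.
#'
#' @param path CSV file path.
#' @param outcome_col name of the outcome column (default `"Target"`).
#' @param remap_outcome coerce a two-valued non-0/1 outcome to 0/1?
#' @return a `radiomics_dataset`.
#' @export
read_dataset <- function(path, outcome_col = "Target", remap_outcome = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = "",
                        stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!outcome_col %in% names(df))
    stop(sprintf("outcome column '%s' not found", outcome_col))
  y_raw <- df[[outcome_col]]
  if (anyNA(y_raw)) stop("outcome column contains missing values")
  sample_ids <- if ("SampleID" %in% names(df)) as.character(df$SampleID) else NULL
  feat_df <- df[, setdiff(names(df), c(outcome_col, "SampleID")), drop = FALSE]
  for (j in seq_along(feat_df)) {
    col <- feat_df[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad))
        stop(sprintf("non-numeric feature cell at row %d, column '%s': '%s'",
                     bad[1], names(feat_df)[j], col[bad[1]]))
      feat_df[[j]] <- num
    }
  }
  vals <- sort(unique(y_raw))
  if (!all(vals %in% c(0, 1))) {
    if (remap_outcome && length(vals) == 2) {
      y_raw <- as.integer(y_raw == vals[2])
    } else {
      stop(sprintf("outcome column must be binary 0/1; observed values: %s",
                   paste(vals, collapse = ", ")))
    }
  }
  new_radiomics_dataset(as.matrix(feat_df), as.integer(y_raw),
                        feature_names = names(feat_df),
                        sample_ids = sample_ids)
}
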