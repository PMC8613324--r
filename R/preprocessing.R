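#' Column-mean imputation
#'
#' Replaces every missing feature cell by the mean of the non-missing values
#' of its column; non-missing cells are untouched. A column with no observed
#' value at all cannot be imputed and raises an error naming it.
#'
#' @param dataset a `radiomics_dataset`, possibly with `NA` cells.
#' @return a list with elements `dataset` (imputed) and `report` (a
#'   `preprocess_report` holding the per-column means used and the number of
#'   imputed cells).
#' @export
impute_mean <- function(dataset) {
  stopifnot(inherits(dataset, "radiomics_dataset"))
  x <- dataset$features
  n_obs <- colSums(!is.na(x))
  if (any(n_obs == 0))
    stop(sprintf("column '%s' is entirely missing and cannot be mean-imputed",
                 dataset$feature_names[which(n_obs == 0)[1]]))
  mu <- colMeans(x, na.rm = TRUE)
  miss <- is.na(x)
  n_imputed <- sum(miss)
  if (n_imputed > 0) {
    idx <- which(miss, arr.ind = TRUE)
    x[miss] <- mu[idx[, 2]]
    dataset$features <- x
  }
  report <- structure(list(column_means = mu, n_imputed_cells = n_imputed),
                      class = "preprocess_report")
  list(dataset = dataset, report = report)
}

#' Z-score normalization
#'
#' Centers every feature column to mean 0 and scales to population standard
#' deviation 1 (divide by N, the common machine-learning scaler convention).
#' Constant columns cannot be scaled: they map to all zeros and are flagged,
#' rather than dropped, so feature indices stay aligned across both training
#' schemes; scorers assign such features the minimal score.
#'
#' Missing cells must be imputed first ([impute_mean()]).
#'
#' @param dataset a `radiomics_dataset` without missing cells.
#' @return a list with `dataset` (standardized) and `report` (centers, scales,
#'   and the indices of constant columns).
#' @export
zscore <- function(dataset) {
  stopifnot(inherits(dataset, "radiomics_dataset"))
  x <- dataset$features
  if (anyNA(x))
    stop("feature matrix contains missing cells; run impute_mean() first")
  n <- nrow(x)
  ctr <- colMeans(x)
  sds <- sqrt(colMeans(x^2) - ctr^2)        # population sd
  sds[sds < .Machine$double.eps^0.5 * pmax(1, abs(ctr))] <- 0
  constant <- which(sds == 0)
  scl <- ifelse(sds == 0, 1, sds)
  x <- sweep(x, 2, ctr, "-")
  x <- sweep(x, 2, scl, "/")
  if (length(constant)) x[, constant] <- 0
  dataset$features <- x
  report <- structure(list(column_centers = ctr, column_scales = scl,
                           constant_columns = constant),
                      class = "preprocess_report")
  list(dataset = dataset, report = report)
}

#' Impute then normalize a whole dataset, up front
#'
#' Convenience pipeline: [impute_mean()] followed by [zscore()], applied once
#' to the complete dataset before any cross-validation. Applying
#' preprocessing to all samples up front is a deliberate design choice of the
#' bias-measurement protocol — fold-wise preprocessing would mix its own
#' (small, outcome-free) leakage into the quantity under study, whereas the
#' feature-selection leak is the effect being isolated. It is NOT the
#' recommended practice for building real predictive models.
#'
#' @param dataset a `radiomics_dataset`.
#' @return a list with `dataset` (preprocessed) and `report` (merged fields of
#'   both steps).
#' @export
preprocess <- function(dataset) {
  imp <- impute_mean(dataset)
  std <- zscore(imp$dataset)
  report <- structure(c(unclass(imp$report), unclass(std$report)),
                      class = "preprocess_report")
  list(dataset = std$dataset, report = report)
}
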