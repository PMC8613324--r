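#' Configure a full bias-measurement experiment
#'
#' Describes a grid of datasets x selectors x selection sizes x classifier
#' configurations, each run under both training schemes with one shared
#' stratified fold assignment per dataset. The defaults reproduce the
#' standard grid shape: 7 selectors x k in {1,2,4,8,16,32} x 7 classifiers x
#' 2 schemes per dataset.
#'
#' @param datasets named list of `radiomics_dataset`s, `dataset_spec`s (to be
#'   generated) or CSV paths (to be read).
#' @param selectors character vector of selector methods.
#' @param k_grid integer vector of selection sizes.
#' @param classifiers character vector of classifier names.
#' @param grids optional hyperparameter-grid overrides for [enumerate_grid()].
#' @param K fold count (default 10).
#' @param seed experiment seed; fans out to generator, fold and classifier
#'   seeds via [derive_seed()].
#' @param n_boot bootstrap repeats for the per-dataset scheme comparison.
#' @param output_dir optional directory for results CSV / comparison JSON and
#'   the resume cache; `NULL` keeps everything in memory.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(datasets,
                              selectors = selector_grid()$methods,
                              k_grid = selector_grid()$k_grid,
                              classifiers = classifier_names(),
                              grids = NULL, K = 10L, seed = 1L,
                              n_boot = 2000L, output_dir = NULL) {
  if (is.null(names(datasets)) || any(names(datasets) == ""))
    names(datasets) <- sprintf("dataset_%02d", seq_along(datasets))
  structure(list(datasets = datasets, selectors = selectors,
                 k_grid = as.integer(k_grid), classifiers = classifiers,
                 grids = grids, K = as.integer(K), seed = as.integer(seed),
                 n_boot = as.integer(n_boot), output_dir = output_dir),
            class = "experiment_config")
}

resolve_dataset <- function(entry) {
  if (inherits(entry, "radiomics_dataset")) entry
  else if (inherits(entry, "dataset_spec")) generate_dataset(entry)
  else if (is.character(entry)) read_dataset(entry)
  else stop("dataset entry must be a radiomics_dataset, dataset_spec or CSV path")
}

cell_key <- function(ds_name, selector, clf, scheme, seed) {
  derive_seed(seed, ds_name, selector$method, selector$k, config_id(clf), scheme)
}

#' Run a full leakage-bias experiment grid
#'
#' For every dataset: preprocess once (whole-dataset imputation and z-scores,
#' by protocol), draw one stratified fold assignment shared by both schemes,
#' then run every (selector, k, classifier-config) cell under Scheme A
#' (selection before CV, leaky) and Scheme B (selection nested per fold).
#' Produces one metrics row per cell and scheme, the per-dataset best-model
#' scheme comparison with paired bootstrap p-values, the per-combination
#' mean-bias matrix, and (when >= 3 datasets) the bias-versus-dimensionality
#' regression.
#'
#' When `output_dir` is set, finished cells are cached as small CSV rows
#' keyed by a provenance hash, so an interrupted run resumes without
#' recomputation, and `results.csv` / `comparisons.json` are written there.
#'
#' @param config an [experiment_config()].
#' @param verbose print one line per dataset?
#' @return list with `results` (data frame), `comparisons` (per-dataset
#'   `scheme_comparison`s), `combination_bias`, and `regression` (or `NULL`).
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  cache_dir <- NULL
  if (!is.null(config$output_dir)) {
    cache_dir <- file.path(config$output_dir, "cache")
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  }
  clf_configs <- enumerate_grid(config$classifiers, grids = config$grids,
                                seed = config$seed)
  rows <- list()
  comparisons <- list()
  reg_points <- list()
  for (ds_name in names(config$datasets)) {
    dataset <- resolve_dataset(config$datasets[[ds_name]])
    if (length(unique(dataset$outcome)) < 2)
      stop(sprintf("dataset '%s' has a single outcome class", ds_name))
    dataset <- preprocess(dataset)$dataset
    folds <- stratified_kfold(dataset$outcome, K = config$K,
                              seed = derive_seed(config$seed, ds_name, "folds"))
    runs_a <- list(); runs_b <- list()
    for (sel_method in config$selectors) {
      for (k in config$k_grid) {
        selector <- list(method = sel_method, k = k)
        for (clf in clf_configs) {
          for (scheme in c("A", "B")) {
            key <- cell_key(ds_name, selector, clf, scheme, config$seed)
            cache_file <- if (!is.null(cache_dir))
              file.path(cache_dir, sprintf("%s.csv", key)) else NULL
            if (!is.null(cache_file) && file.exists(cache_file)) {
              # completed cell: restore pooled probabilities, skip the fits
              cached <- utils::read.csv(cache_file, stringsAsFactors = FALSE)
              run <- new_pooled_predictions(
                cached$prob, dataset$outcome, folds, scheme,
                provenance = list(selector = selector,
                                  classifier = config_id(clf),
                                  classifier_config = clf))
            } else {
              run <- run_or_skip(dataset, selector, clf, folds, scheme)
              if (is.null(run)) next
              if (!is.null(cache_file))
                utils::write.csv(data.frame(prob = run$probs), cache_file,
                                 row.names = FALSE)
            }
            ev <- evaluate_predictions(run)
            rows[[length(rows) + 1]] <- data.frame(
              dataset = ds_name, scheme = scheme, selector = sel_method,
              k = min(k, ncol(dataset$features)), classifier = clf$name,
              config = config_id(clf),
              auc_roc = ev$auc_roc, auc_pr = ev$auc_pr,
              accuracy = ev$accuracy, sensitivity = ev$sensitivity,
              specificity = ev$specificity, precision = ev$precision,
              recall = ev$recall, cell_key = key)
            if (scheme == "A") runs_a[[length(runs_a) + 1]] <- run
            else runs_b[[length(runs_b) + 1]] <- run
          }
        }
      }
    }
    cmp <- compare_schemes(runs_a, runs_b, n_boot = config$n_boot,
                           seed = derive_seed(config$seed, ds_name, "boot"))
    comparisons[[ds_name]] <- cmp
    reg_points[[ds_name]] <- data.frame(
      dataset = ds_name, samples_per_feature = samples_per_feature(dataset),
      bias = unname(cmp$delta["auc_roc"]))
    if (verbose)
      message(sprintf("%s: best A = %.3f, best B = %.3f, bias = %.3f",
                      ds_name, cmp$best_a$auc_roc, cmp$best_b$auc_roc,
                      cmp$delta["auc_roc"]))
  }
  results <- do.call(rbind, rows)
  points <- do.call(rbind, reg_points)
  regression <- if (nrow(points) >= 3 && stats::sd(points$samples_per_feature) > 0)
    bias_vs_dimensionality(points) else NULL
  out <- list(results = results, comparisons = comparisons,
              combination_bias = combination_bias(results),
              regression = regression)
  if (!is.null(config$output_dir)) {
    utils::write.csv(results, file.path(config$output_dir, "results.csv"),
                     row.names = FALSE)
    cmp_json <- lapply(comparisons, function(cmp) list(
      best_a = cmp$best_a[c("auc_roc", "auc_pr", "accuracy")],
      best_b = cmp$best_b[c("auc_roc", "auc_pr", "accuracy")],
      delta = as.list(cmp$delta), p_values = as.list(cmp$p_values)))
    jsonlite::write_json(cmp_json,
                         file.path(config$output_dir, "comparisons.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# A grid cell whose classifier cannot be fitted (e.g. a degenerate training
# fold) is skipped with a message rather than aborting the whole grid.
run_or_skip <- function(dataset, selector, clf, folds, scheme) {
  tryCatch({
    if (scheme == "A") run_scheme_a(dataset, selector, clf, folds)
    else run_scheme_b(dataset, selector, clf, folds)
  }, error = function(e) {
    message(sprintf("skipped %s/%s k=%d scheme %s: %s", selector$method,
                    config_id(clf), selector$k, scheme, conditionMessage(e)))
    NULL
  })
}
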