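#' @title Classifier zoo
#' @description Seven classifiers behind a single contract: `fit_classifier()`
#'   takes a `classifier_config`, a training matrix and 0/1 labels and
#'   returns a fitted model whose `predict_proba()` maps an M x k matrix to M
#'   probabilities of the positive class in `[0, 1]`, deterministically given
#'   the config seed. Every classifier emits calibrated probabilities (the
#'   SVM through its internal probability model) so pooled micro-averaged
#'   metrics compare like with like across classifiers and folds.
#' @name model_zoo
NULL

classifier_names <- function() {
  c("logistic", "random_forest", "rbf_svm", "neural_net", "xgb_tree",
    "naive_bayes", "constant")
}

# Hyperparameter grids. The protocol deliberately tunes only a handful of
# hyperparameters per classifier; naive Bayes and the constant-majority
# baseline have none.
default_grids <- function() {
  list(
    logistic = list(C = c(0.01, 0.1, 1, 10)),
    random_forest = list(num_trees = c(100L, 500L), max_depth = c(0L, 5L)),
    rbf_svm = list(C = c(0.1, 1, 10), gamma = c(NA_real_, 0.01)),  # NA = scale heuristic
    neural_net = list(hidden = c(16L, 64L), decay = c(1e-4, 1e-2)),
    xgb_tree = list(max_depth = c(2L, 4L), nrounds = 100L, eta = c(0.1, 0.3)),
    naive_bayes = list(),
    constant = list()
  )
}

new_classifier_config <- function(name, hyperparameters = list(), seed = 1L) {
  structure(list(name = name, hyperparameters = hyperparameters,
                 seed = as.integer(seed)), class = "classifier_config")
}

config_id <- function(config) {
  hp <- config$hyperparameters
  if (!length(hp)) return(config$name)
  paste0(config$name, "[",
         paste(sprintf("%s=%s", names(hp),
                       vapply(hp, function(v) format(v, digits = 6),
                              character(1))), collapse = ","), "]")
}

#' Enumerate classifier configurations over the default grids
#'
#' Builds the deterministic cross-product of each named classifier's
#' hyperparameter grid, in a stable order (classifiers in the given order,
#' grid points lexicographic by parameter name) so downstream tie-breaking
#' is reproducible. Naive Bayes and the constant baseline each contribute
#' exactly one configuration.
#'
#' @param names character vector of classifier names (subset of
#'   [classifier_names()]).
#' @param grids optional named list overriding the default grids
#'   (name -> list(parameter -> values)).
#' @param seed seed stored in every config (refined per fold by the engine).
#' @return a list of `classifier_config` objects.
#' @export
enumerate_grid <- function(names, grids = NULL, seed = 1L) {
  all_grids <- utils::modifyList(default_grids(), grids %||% list())
  unknown <- setdiff(names, classifier_names())
  if (length(unknown))
    stop(sprintf("unknown classifier name(s): %s", paste(unknown, collapse = ", ")))
  configs <- list()
  for (nm in names) {
    g <- all_grids[[nm]]
    if (!length(g)) {
      configs <- c(configs, list(new_classifier_config(nm, seed = seed)))
      next
    }
    g <- g[order(names(g))]
    cells <- expand.grid(rev(g), stringsAsFactors = FALSE)
    cells <- cells[, rev(seq_along(g)), drop = FALSE]
    for (i in seq_len(nrow(cells))) {
      hp <- as.list(cells[i, , drop = FALSE]); names(hp) <- names(g)
      configs <- c(configs, list(new_classifier_config(nm, hp, seed = seed)))
    }
  }
  configs
}

#' Fit a classifier under the shared probability contract
#'
#' Trains the classifier named in `config` on `x_train`/`y_train`. All
#' classifiers except the constant baseline require both classes in the
#' training labels. The constant classifier ignores the features entirely
#' and predicts the training-majority class with probability one (ties go to
#' class 0).
#'
#' @param config a `classifier_config` from [enumerate_grid()] (or built with
#'   the same fields).
#' @param x_train N x k numeric training matrix.
#' @param y_train length-N 0/1 training labels.
#' @return a `fitted_model`; call [predict_proba()] on it.
#' @export
fit_classifier <- function(config, x_train, y_train) {
  x_train <- as.matrix(x_train)
  if (is.null(colnames(x_train)))
    colnames(x_train) <- sprintf("V%d", seq_len(ncol(x_train)))
  y_train <- as.integer(y_train)
  hp <- config$hyperparameters
  if (config$name != "constant" && length(unique(y_train)) < 2)
    stop(sprintf("classifier '%s' needs both classes in the training data",
                 config$name))
  model <- switch(config$name,
    constant = {
      n1 <- sum(y_train == 1L)
      list(p = as.numeric(n1 > length(y_train) - n1))  # tie -> class 0
    },
    logistic = fit_logistic(x_train, y_train, C = hp$C %||% 1),
    naive_bayes = e1071::naiveBayes(
      x = as.data.frame(x_train), y = factor(y_train, levels = c(0, 1))),
    rbf_svm = {
      gamma <- hp$gamma %||% NA_real_
      if (is.na(gamma)) {
        v <- mean(apply(x_train, 2, stats::var))
        gamma <- 1 / (ncol(x_train) * max(v, .Machine$double.eps))
      }
      with_seed(config$seed,
        e1071::svm(x_train, factor(y_train, levels = c(0, 1)),
                   kernel = "radial", cost = hp$C %||% 1, gamma = gamma,
                   probability = TRUE, scale = FALSE))
    },
    random_forest = {
      df <- data.frame(x_train)
      df$.y <- factor(y_train, levels = c(0, 1))
      ranger::ranger(.y ~ ., data = df, probability = TRUE,
                     num.trees = hp$num_trees %||% 500L,
                     max.depth = hp$max_depth %||% 0L,
                     seed = config$seed, num.threads = 1L)
    },
    neural_net = with_seed(config$seed,
      nnet::nnet(x_train, y_train, size = hp$hidden %||% 16L,
                 decay = hp$decay %||% 1e-4, entropy = TRUE, maxit = 200,
                 MaxNWts = 100000, trace = FALSE)),
    xgb_tree = {
      dtrain <- xgboost::xgb.DMatrix(x_train, label = y_train)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp$max_depth %||% 4L,
                      eta = hp$eta %||% 0.1, nthread = 1L,
                      seed = config$seed),
        data = dtrain, nrounds = hp$nrounds %||% 100L, verbose = 0)
    },
    stop(sprintf("unknown classifier name '%s'", config$name))
  )
  structure(list(config = config, model = model,
                 colnames = colnames(x_train)), class = "fitted_model")
}

# Ridge-penalized logistic regression (penalty 1/(C*N) on the L2 norm),
# stable when k approaches the training size. glmnet needs >= 2 columns, so a
# single-feature design is padded with an all-zero column whose coefficient
# is identically zero.
fit_logistic <- function(x, y, C = 1) {
  padded <- ncol(x) < 2
  if (padded) x <- cbind(x, .pad = 0)
  lam <- 1 / (C * nrow(x))
  # glmnet warns on very small classes; harmless for the toy sizes used here
  fit <- suppressWarnings(
    glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                   alpha = 0, lambda = lam, standardize = FALSE))
  list(fit = fit, lambda = lam, padded = padded)
}

#' Predict positive-class probabilities
#'
#' @param object a `fitted_model` from [fit_classifier()].
#' @param x_new M x k matrix on the same features used for training.
#' @return length-M numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(object, x_new) {
  stopifnot(inherits(object, "fitted_model"))
  x_new <- as.matrix(x_new)
  if (is.null(colnames(x_new)))
    colnames(x_new) <- sprintf("V%d", seq_len(ncol(x_new)))
  m <- object$model
  p <- switch(object$config$name,
    constant = rep(m$p, nrow(x_new)),
    logistic = {
      if (m$padded) x_new <- cbind(x_new, .pad = 0)
      as.numeric(stats::predict(m$fit, newx = x_new, s = m$lambda,
                                type = "response"))
    },
    naive_bayes = {
      df <- as.data.frame(x_new)
      names(df) <- object$colnames
      as.numeric(stats::predict(m, df, type = "raw")[, "1"])
    },
    rbf_svm = {
      pr <- stats::predict(m, x_new, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "1"])
    },
    random_forest = {
      df <- data.frame(x_new)
      as.numeric(stats::predict(m, data = df, num.threads = 1L)$predictions[, "1"])
    },
    neural_net = as.numeric(stats::predict(m, x_new)),
    xgb_tree = as.numeric(stats::predict(m, xgboost::xgb.DMatrix(x_new)))
  )
  pmin(pmax(p, 0), 1)
}
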