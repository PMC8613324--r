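test_that("AUC-ROC matches hand-computed and limiting cases", {
  expect_equal(auc_roc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_roc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auc_roc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_error(auc_roc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC-ROC equals the brute-force pair-counting oracle", {
  set.seed(51)
  for (trial in 1:60) {
    n <- sample(10:60, 1)
    y <- c(0, 1, rbinom(n - 2, 1, runif(1, 0.2, 0.8)))
    p <- round(runif(n), sample(1:3, 1))      # coarse rounding forces ties
    expect_identical(auc_roc(p, y), auc_bruteforce(p, y))
  }
})

test_that("AUC-ROC agrees with pROC on continuous scores", {
  set.seed(52)
  y <- rbinom(100, 1, 0.4); y[1:2] <- c(0, 1)
  p <- runif(100)
  expect_equal(auc_roc(p, y),
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("average precision matches the step rule by hand", {
  expect_equal(auc_pr(c(0.9, 0.8, 0.7), c(1, 0, 1)), 5 / 6)
  expect_equal(auc_pr(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  set.seed(53)
  y <- rep(c(0, 1), 1000)
  expect_lt(abs(auc_pr(runif(2000), y) - 0.5), 0.05)  # null AP ~ prevalence
  expect_error(auc_pr(c(0.5, 0.4), c(0, 0)), "positive")
})

test_that("ranking metrics are invariant under strictly increasing transforms", {
  set.seed(54)
  p <- runif(50); y <- rep(c(0, 1), 25)
  for (f in list(function(z) z^3, function(z) exp(2 * z), plogis)) {
    expect_equal(auc_roc(f(p), y), auc_roc(p, y), tolerance = 1e-12)
    expect_equal(auc_pr(f(p), y), auc_pr(p, y), tolerance = 1e-12)
  }
})

test_that("threshold metrics recover the confusion-matrix identities", {
  m <- threshold_metrics(c(0.6, 0.4), c(1, 0))
  expect_equal(m$accuracy, 1)
  all_pos <- threshold_metrics(rep(1, 10), c(rep(1, 6), rep(0, 4)))
  expect_equal(all_pos$accuracy, 0.6)
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  expect_equal(all_pos$recall, all_pos$sensitivity)
  none_pos <- threshold_metrics(rep(0, 4), c(1, 0, 1, 0))
  expect_equal(none_pos$precision, 0)    # empty positive set -> 0 by contract
})

test_that("best-model selection uses the metric with stable tie-breaking", {
  r <- function(a) structure(list(auc_roc = a), class = "evaluation_result")
  expect_equal(select_best(list(r(0.7), r(0.9))), 2L)
  expect_equal(select_best(list(r(0.8), r(0.8), r(0.5))), 1L)
  expect_equal(select_best(list(r(0.8))), 1L)
  expect_error(select_best(list()), "non-empty")
})

test_that("identical scheme runs give zero bias and p = 1", {
  y <- rep(c(0L, 1L), 20)
  p <- plogis(rnorm(40))
  a <- make_preds(p, y, "A"); b <- make_preds(p, y, "B")
  cmp <- compare_schemes(list(a), list(b), n_boot = 200, seed = 1)
  expect_equal(unname(cmp$delta), c(0, 0, 0))
  expect_equal(unname(cmp$p_values), c(1, 1, 1))
})

test_that("the paired bootstrap p-value floor and pairing contract hold", {
  set.seed(55)
  y <- rep(c(0L, 1L), 50)
  pa <- ifelse(y == 1, runif(100, 0.5, 1), runif(100, 0, 0.5))  # strong model
  pb <- runif(100)                                              # random model
  p <- bootstrap_delta_test(make_preds(pa, y), make_preds(pb, y),
                            metrics = "auc_roc", n_boot = 500, seed = 2)
  expect_gte(p[["auc_roc"]], 2 / 500)
  expect_lt(p[["auc_roc"]], 0.05)
  mismatched <- make_preds(pb, rev(y))
  expect_error(bootstrap_delta_test(make_preds(pa, y), mismatched), "labels")
})

test_that("the combination bias matrix averages per-combination best models", {
  rows <- expand.grid(dataset = c("d1", "d2"), scheme = c("A", "B"),
                      selector = "t_score", classifier = "logistic",
                      stringsAsFactors = FALSE)
  rows$auc_roc <- c(0.9, 0.8, 0.6, 0.7)   # d1: A .9 B .6; d2: A .8 B .7
  cb <- combination_bias(rows)
  expect_equal(nrow(cb), 1)
  expect_equal(cb$mean_bias, mean(c(0.3, 0.1)))
  expect_equal(cb$min_bias, 0.1)
  expect_equal(cb$max_bias, 0.3)
  # swapping scheme labels negates the cell
  rows2 <- rows; rows2$scheme <- ifelse(rows$scheme == "A", "B", "A")
  expect_equal(combination_bias(rows2)$mean_bias, -cb$mean_bias)
  # the constant classifier column is exactly zero
  rowsc <- rows; rowsc$classifier <- "constant"; rowsc$auc_roc <- rep(0.5, 4)
  expect_equal(combination_bias(rowsc)$mean_bias, 0)
})

test_that("the dimensionality regression recovers a perfect line and rejects degenerate x", {
  pts <- data.frame(samples_per_feature = c(0.1, 1, 5))
  pts$bias <- 0.4 - 0.1 * pts$samples_per_feature
  reg <- bias_vs_dimensionality(pts)
  expect_equal(reg$pearson_r, -1, tolerance = 1e-12)
  expect_lt(reg$slope, 0)
  expect_lt(reg$p_value, 1e-6)
  expect_equal(sign(reg$slope), sign(reg$pearson_r))
  expect_error(bias_vs_dimensionality(pts[1:2, ]), "3 points")
  pts$samples_per_feature <- 1
  expect_error(bias_vs_dimensionality(pts), "constant")
})
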