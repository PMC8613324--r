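test_that("the Welch t scorer matches the direct formula and its symmetries", {
  x <- cbind(f = c(1, 2, 3, 4))
  y <- c(0, 0, 1, 1)
  # sample variances 0.5 in each class: |t| = 2 / sqrt(0.5/2 + 0.5/2)
  expect_equal(score_t(x, y)$scores, 2 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(score_t(x, 1 - y)$scores, score_t(x, y)$scores)
  expect_equal(score_t(cbind(c(3, 3, 3, 3)), y)$scores, 0)
  expect_error(score_t(x, c(1, 1, 1, 1)), "single class")
})

test_that("F scores rank identically to squared pooled t on random data", {
  set.seed(31)
  for (trial in 1:50) {
    n <- sample(20:60, 1); d <- 8
    x <- matrix(rnorm(n * d), n, d)
    y <- c(rep(0, n %/% 2), rep(1, n - n %/% 2))
    f <- score_f(x, y)$scores
    t2 <- apply(x, 2, pooled_t, y = y)^2
    expect_equal(order(f), order(t2))
    expect_equal(f, t2, tolerance = 1e-8)  # two-group identity F = t^2
  }
})

test_that("degenerate features get capped, not infinite, F and t scores", {
  x <- cbind(sep = c(0, 0, 1, 1), noise = c(0.3, -0.2, 0.1, 0.4),
             flat = c(5, 5, 5, 5))
  y <- c(0, 0, 1, 1)
  f <- score_f(x, y)$scores
  expect_true(all(is.finite(f)))
  expect_gt(f[1], f[2])   # perfectly separated feature ranks top
  expect_equal(f[3], 0)
})

test_that("MIM equals ln 2 for a perfect binary predictor and is monotone-invariant", {
  y <- rep(c(0, 1), each = 20)
  x <- cbind(perfect = y + 0, junk = rep(c(0.1, 0.9), 20))
  s <- score_mim(x, y, n_bins = 2)$scores
  expect_equal(s[1], log(2), tolerance = 1e-12)
  # null features: plug-in MI bias ~ (bins-1)/(2N) nats
  set.seed(11)
  nulls <- replicate(50, {
    score_mim(cbind(rnorm(40)), rep(c(0, 1), each = 20), n_bins = 10)$scores
  })
  expect_lt(mean(nulls), 3 * (10 - 1) / (2 * 40))
  # strictly monotone transform leaves equal-frequency bins unchanged
  set.seed(12)
  xx <- cbind(rnorm(100))
  yy <- rbinom(100, 1, 0.5)
  expect_equal(score_mim(xx, yy)$scores, score_mim(exp(xx), yy)$scores)
  expect_equal(score_mim(xx, yy)$scores, score_mim(atan(xx) * 7 - 2, yy)$scores)
})

test_that("ReliefF rewards separating features and ignores constants", {
  set.seed(21)
  y <- rep(c(0, 1), each = 20)
  x <- cbind(sep = y + 0, noise = rnorm(40), flat = rep(2, 40))
  w <- score_relieff(x, y, n_neighbors = 5)$scores
  expect_gt(w[1], w[2])
  expect_equal(w[3], 0)
  # permutation of sample order leaves all-anchor weights unchanged
  perm <- sample(40)
  w2 <- score_relieff(x[perm, ], y[perm], n_neighbors = 5)$scores
  expect_equal(w2, w, tolerance = 1e-12)
  expect_error(score_relieff(x, y, n_neighbors = 25), "class")
})

test_that("greedy mRMR starts at max relevance and punishes redundancy", {
  set.seed(41)
  y <- rep(c(0, 1), each = 50)
  a <- y + rnorm(100, sd = 0.5)          # strong signal
  b <- y + rnorm(100, sd = 2)            # weaker independent signal
  x <- cbind(A = a, Aprime = a, B = b)   # Aprime duplicates A exactly
  s <- score_mrmr(x, y, k = 3)
  rel <- score_mim(x, y)$scores
  expect_equal(s$selected_order[1], which.max(rel))
  # the duplicate is fully redundant with the first pick; B goes second
  expect_equal(s$selected_order[2], 3L)
  full <- score_mrmr(x, y, k = 3)$selected_order
  expect_setequal(full, 1:3)             # k = d exhausts all features
})

test_that("LASSO entry order finds planted signal and falls back gracefully", {
  hits <- sapply(1:20, function(s) {
    ds <- generate_dataset(dataset_spec(200, 21, prevalence = 0.5,
                                        n_informative = 1, effect_size = 2,
                                        seed = s))
    pp <- preprocess(ds)$dataset
    score_lasso(pp$features, pp$outcome)$selected_order[1] == 1L
  })
  expect_gte(mean(hits), 0.95)
  # duplicated informative feature: one duplicate enters first, both beat noise
  set.seed(17)
  y <- rep(c(0, 1), each = 50)
  sig <- y + rnorm(100, sd = 0.7)
  x <- scale(cbind(sig, sig, matrix(rnorm(100 * 5), 100, 5)))
  ord <- score_lasso(x, y)$selected_order
  expect_true(ord[1] %in% 1:2)
  expect_true(all(match(1:2, ord) <= 4))
  # pure noise: ranking still a valid permutation
  xn <- matrix(rnorm(60 * 4), 60, 4)
  expect_setequal(score_lasso(xn, rep(c(0, 1), each = 30))$selected_order, 1:4)
})

test_that("SVM-RFE keeps a perfect separator to the end", {
  for (s in 1:5) {
    set.seed(s)
    y <- rep(c(0, 1), each = 20)
    x <- cbind(noise = rnorm(40), sep = y * 2 - 1)
    ord <- score_svm_rfe(x, y)$selected_order
    expect_equal(ord[1], 2L)
    expect_setequal(ord, 1:2)
  }
  # d = 1: trivially ranked first
  one <- score_svm_rfe(cbind(rnorm(40)), rep(c(0, 1), each = 20))
  expect_equal(one$selected_order, 1L)
  # elimination order is a permutation at larger d (crosses the halving phase)
  set.seed(9)
  x <- matrix(rnorm(60 * 100), 60, 100)
  expect_setequal(score_svm_rfe(x, rep(c(0, 1), each = 30))$selected_order,
                  1:100)
})

test_that("select_top_k honours scores, orders, ties and capping", {
  s <- foldleak:::new_feature_score(c(0.9, 0.1, 0.5), "t_score")
  expect_equal(select_top_k(s, 2), c(1L, 3L))
  ties <- foldleak:::new_feature_score(c(1, 1, 1), "t_score")
  expect_equal(select_top_k(ties, 2), c(1L, 2L))
  expect_warning(sel <- select_top_k(s, 64), "capped")
  expect_equal(sel, 1:3)
  ordered <- foldleak:::new_feature_score(c(3, 2, 1), "mrmr",
                                          selected_order = c(2L, 3L, 1L))
  expect_equal(select_top_k(ordered, 2), c(2L, 3L))
})

test_that("every scorer is equivariant under feature permutation", {
  ds <- signal_dataset(n = 60, d = 12, n_informative = 2, seed = 8)
  x <- ds$features; y <- ds$outcome
  perm <- c(5, 1, 12, 3, 9, 2, 7, 11, 4, 10, 6, 8)
  for (m in selector_grid()$methods) {
    s1 <- score_features(x, y, m, k = 12)$scores
    s2 <- score_features(x[, perm], y, m, k = 12)$scores
    expect_equal(s2, s1[perm], tolerance = 1e-9, label = m)
  }
})

test_that("no feature is favoured on exchangeable null data", {
  d <- 20
  top1 <- sapply(1:200, function(s) {
    ds <- generate_dataset(dataset_spec(60, d, prevalence = 0.5, seed = 4000 + s))
    which.max(score_t(ds$features, ds$outcome)$scores)
  })
  count1 <- sum(top1 == 1)               # a fixed feature's top-1 frequency
  bounds <- qbinom(c(0.005, 0.995), 200, 1 / d)
  expect_gte(count1, bounds[1])
  expect_lte(count1, bounds[2])
})
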