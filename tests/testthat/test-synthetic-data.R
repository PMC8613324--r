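test_that("invalid specs are rejected with the offending field named", {
  expect_error(dataset_spec(100, 50, prevalence = 1.2), "prevalence")
  expect_error(dataset_spec(100, 50, prevalence = 0), "prevalence")
  expect_error(dataset_spec(100, 50, n_informative = 60), "n_informative")
  expect_error(dataset_spec(100, 50, missing_rate = 0.05), "missing_rate")
  expect_error(dataset_spec(100, 50, within_block_correlation = 1),
               "within_block_correlation")
  expect_error(dataset_spec(100, 50, block_size = 51), "block_size")
})

test_that("generation is deterministic given the spec seed", {
  spec <- dataset_spec(60, 40, prevalence = 0.4, n_informative = 3,
                       effect_size = 0.8, block_size = 5,
                       within_block_correlation = 0.5, seed = 99)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a, b)
  c <- generate_dataset(dataset_spec(60, 40, prevalence = 0.4, seed = 100))
  expect_false(identical(a$features, c$features))
})

test_that("null datasets carry no feature-outcome association", {
  ds <- generate_dataset(dataset_spec(100, 1000, prevalence = 0.5, seed = 7))
  cors <- as.numeric(cor(ds$features, ds$outcome))
  expect_lt(abs(mean(cors)), 3 / sqrt(100))
  expect_identical(ds$informative, integer(0))
})

test_that("informative features carry the prescribed standardized shift", {
  # expected |t| of a feature shifted by delta sd at balanced N:
  # delta * sqrt(N/4) = 1 * sqrt(200/4) ~ 7.07; mean over 20 seeds within 1
  tstats <- sapply(1:20, function(s) {
    ds <- generate_dataset(dataset_spec(200, 50, prevalence = 0.5,
                                        n_informative = 8, effect_size = 1,
                                        seed = s))
    mean(abs(score_t(ds$features[, 1:8], ds$outcome)$scores))
  })
  expect_lt(abs(mean(tstats) - sqrt(200 / 4)), 1)
})

test_that("within-block correlations match the requested level", {
  ds <- generate_dataset(dataset_spec(2000, 20, prevalence = 0.5,
                                      block_size = 5,
                                      within_block_correlation = 0.9,
                                      seed = 5))
  block_cors <- unlist(lapply(0:3, function(b) {
    cm <- cor(ds$features[, b * 5 + 1:5])
    cm[upper.tri(cm)]
  }))
  expect_lt(abs(mean(block_cors) - 0.9), 0.05)
  # across blocks features are uncorrelated
  expect_lt(abs(mean(cor(ds$features[, 1:5], ds$features[, 6:10]))), 0.05)
})

test_that("outcome uses exact-count assignment at the requested prevalence", {
  for (prev in c(0.28, 0.5, 0.73)) {
    ds <- generate_dataset(dataset_spec(107, 10, prevalence = prev, seed = 3))
    expect_lte(abs(sum(ds$outcome) - round(107 * prev)), 1)
    expect_true(all(ds$outcome %in% 0:1))
  }
})

test_that("generator type-I error is calibrated on null data", {
  # fraction of features with two-sample t-test p < 0.05 should be ~ 0.05
  fracs <- sapply(1:50, function(s) {
    ds <- generate_dataset(dataset_spec(40, 100, prevalence = 0.5, seed = s))
    ps <- apply(ds$features, 2, function(col)
      t.test(col[ds$outcome == 1], col[ds$outcome == 0])$p.value)
    mean(ps < 0.05)
  })
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
})

test_that("inject_missing masks cells at the requested rate, never the outcome", {
  ds <- generate_dataset(dataset_spec(100, 1000, prevalence = 0.5, seed = 2))
  expect_identical(inject_missing(ds, 0), ds)
  dm <- inject_missing(ds, 0.005, seed = 4)
  n_miss <- sum(is.na(dm$features))
  expect_lt(abs(n_miss - 500), 3 * sqrt(500 * 0.995))
  expect_identical(dm$outcome, ds$outcome)
  expect_true(all(colSums(!is.na(dm$features)) >= 1))
  expect_error(inject_missing(ds, 0.05), "missing_rate")
})

test_that("CSV write/read round trip reproduces the dataset", {
  ds <- inject_missing(
    generate_dataset(dataset_spec(20, 10, prevalence = 0.5, seed = 6)),
    0.01, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$features, ds$features, tolerance = 1e-12)
  expect_identical(back$outcome, ds$outcome)
  expect_identical(back$feature_names, ds$feature_names)
  expect_identical(back$sample_ids, ds$sample_ids)
  expect_identical(is.na(back$features), is.na(ds$features))
})

test_that("malformed CSVs are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SampleID,f1,f2,Target", "s1,0.5,1.0,1", "s2,0.1,2.0,2",
               "s3,0.2,1.5,1"), path)
  expect_error(read_dataset(path), "1, 2")
  remapped <- read_dataset(path, remap_outcome = TRUE)
  expect_identical(remapped$outcome, c(0L, 1L, 0L))  # sorted order: 1->0, 2->1
  writeLines(c("SampleID,f1,Target", "s1,abc,1", "s2,0.1,0"), path)
  expect_error(read_dataset(path), "row 1.*f1")
  writeLines(c("SampleID,f1,Target", "s1,,1", "s2,0.1,0"), path)
  ds <- read_dataset(path)
  expect_true(is.na(ds$features[1, 1]))
})
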