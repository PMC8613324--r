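# foldleak

Measuring the optimism bias that data leakage from feature selection
introduces into cross-validated performance estimates of high-dimensional
tabular classifiers.

## The problem

Radiomics and similar biomarker studies model a binary clinical outcome from
feature tables with far more features than samples (d ≫ N, often fewer than
0.1 samples per feature). Because most features are irrelevant, a filter
feature-selection step keeps only the top-k features before a classifier is
fitted, and k-fold cross-validation (CV) is used to estimate performance.
If the selection step is run **once on the whole dataset before CV**, the
held-out folds have already contributed their outcome labels to the
selection — a data leak — and the pooled CV estimate is optimistically
biased. `foldleak` quantifies that bias by running identical modeling grids
under two schemes:

- **Scheme A (leaky)** — score features on all N samples, select the top k,
  then cross-validate the classifier on the selected columns;
- **Scheme B (correct)** — re-score and re-select inside every fold on the
  K−1 training folds only, so no validation fold ever touches the selection.

Both schemes share one stratified tenfold split, and out-of-fold
probabilities are pooled (micro-averaged) before computing AUC-ROC, the
area under the precision–recall curve and accuracy. The **bias** for a
dataset is

> Δ = metric(best model under Scheme A) − metric(best model under Scheme B),

where "best" means highest pooled AUC-ROC within the scheme. A paired
bootstrap (2000 resamples of the N cases, two-sided percentile tail) tests
Δ = 0, and across datasets the bias is regressed on the samples-per-feature
ratio N/d (Pearson correlation, OLS slope, t-test with n−2 df).

The package provides, as testable modules:

- a synthetic-data generator (block-correlated Gaussian features, exact-count
  outcome prevalence, optional planted signal, sub-1% missingness) plus
  CSV read/write for real feature tables;
- whole-dataset preprocessing (column-mean imputation, z-scores) — applied
  up front *by protocol*, so the measured bias isolates the selection leak;
- seven filter selectors: absolute Welch t, ANOVA F, mutual-information
  maximization (equal-frequency bins), ReliefF, greedy mRMR, LASSO
  entry-order ranking, and linear SVM-RFE, with k ∈ {1, 2, 4, 8, 16, 32};
- seven classifiers behind one fit/predict-probability contract: ridge
  logistic regression, random forest, RBF-SVM, a one-hidden-layer neural
  network, gradient-boosted trees, Gaussian naive Bayes and a
  constant-majority baseline (which, ignoring features, is provably immune
  to selection leakage);
- the two CV schemes, the bias statistics, the per-(selector × classifier)
  mean-bias matrix and the bias-vs-dimensionality regression, orchestrated
  by `run_experiment()` with caching and resumability.

## Worked example

Pure-noise data — no feature has any real association with the outcome, so
the true AUC-ROC of any classifier is 0.5:

```r
library(foldleak)
ds <- preprocess(generate_dataset(
  dataset_spec(100, 1000, prevalence = 0.5, seed = 7)))$dataset
folds <- stratified_kfold(ds$outcome, K = 10, seed = 11)
sel <- list(method = "t_score", k = 32)
clf <- enumerate_grid("logistic", grids = list(logistic = list(C = 1)))[[1]]
cmp <- compare_schemes(
  list(run_scheme_a(ds, sel, clf, folds)),
  list(run_scheme_b(ds, sel, clf, folds)),
  n_boot = 2000, seed = 13)
round(c(auc_A = cmp$best_a$auc_roc, auc_B = cmp$best_b$auc_roc,
        bias = cmp$delta[["auc_roc"]], p = cmp$p_values[["auc_roc"]]), 3)
#> auc_A auc_B  bias     p
#> 0.928 0.445 0.483 0.001
```

The nested scheme correctly reports chance performance (0.445); the leaky
scheme reports an apparently excellent classifier (0.928) that does not
exist. The difference, 0.483 in AUC-ROC, is pure selection leakage, and the
paired bootstrap flags it as highly significant.

The numbered drivers under `analysis/` run the full study on synthetic
data: `01_simulate_datasets.R` (the dataset battery),
`02_leakage_bias.R` (the 20-seed headline simulation above),
`03_dimensionality.R` (bias vs samples-per-feature sweep and regression)
and `04_grid_experiment.R` (a selector × classifier grid with the
per-combination bias matrix). Each writes its tables under `results/`.

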