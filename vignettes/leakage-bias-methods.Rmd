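---
title: "Measuring selection-leakage bias in cross-validated radiomics models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring selection-leakage bias: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedure `foldleak` implements,
the modeling assumptions behind its synthetic-data generator, and the design
decisions taken where the procedure leaves genuine freedom. The numbered
scripts under `analysis/` are the runnable account of the results; nothing
below states an empirical number that those scripts or the test suite do not
themselves compute.

## The quantity being measured

High-dimensional tabular classification pipelines in radiomics typically
(1) select the top-k features by a filter criterion and (2) estimate
performance by stratified k-fold cross-validation with pooled
(micro-averaged) out-of-fold predictions. When step (1) is run once on the
complete dataset, every validation fold has already contributed its outcome
labels to the selection. The package measures the consequence by running the
*same* grid of (selector, k, classifier) cells twice:

* **Scheme A** — features scored once on all N samples; the single selected
  feature set is reused in every fold;
* **Scheme B** — features re-scored within each fold on the K−1 training
  folds only.

For one dataset, the **bias** is the per-metric difference between the
best-AUC-ROC model of scheme A and the best-AUC-ROC model of scheme B.
Selecting the best model *within each scheme* (rather than comparing a fixed
cell) mirrors how studies actually report results: the winning pipeline of a
grid search. The per-combination matrix produced by `combination_bias()`
covers the complementary reading — a study that fixed one selector and one
classifier in advance.

Both schemes share one stratified fold assignment per dataset. The
procedure does not require this, but pairing the schemes on identical folds
removes fold-composition noise from the A−B difference, so the contrast
isolates the leak; the choice is recorded here because it sharpens, never
biases, the comparison.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` emulates the statistical shape of published radiomics
feature tables:

* **Dimensionality** — N from tens to hundreds, d up to thousands, i.e.
  samples-per-feature ratios down to 0.01;
* **Redundancy** — features drawn in equicorrelated blocks via a shared
  latent factor (`x = sqrt(rho) z_block + sqrt(1-rho) eps`), giving exactly
  the requested pairwise correlation inside a block with one parameter;
* **Prevalence** — outcome positives fixed at `round(N * prevalence)` by
  exact-count assignment and then shuffled. Bernoulli draws would make
  class counts random, which complicates stratification edge cases without
  adding realism; the deterministic count makes fold-invariant tests exact.
* **Signal** — an optional planted effect: the first `n_informative`
  columns get their class-1 mean raised by `effect_size` standard
  deviations. Real feature tables have no ground-truth "informative set";
  the planted indices exist purely so recovery tests can verify the
  scorers. With `n_informative = 0` the dataset is exactly null, and any
  positive cross-validated AUC excess is attributable to the pipeline, not
  the data — this is the generator's main analytical role.
* **Missingness** — independent per-cell masking at a rate capped at 1%,
  matching the sparse numerical-failure missingness of radiomics feature
  extraction. The cap is enforced, not merely defaulted, because the
  imputation strategy (column means) is only defensible in that regime.

What the generator does **not** emulate: heavy-tailed and skewed marginal
distributions, feature-wise scale heterogeneity (washed out here by
z-scoring anyway), nonlinear feature-outcome relationships, and the
long-range correlation structure of real radiomics features beyond
single-level blocks. Consequently, passing tests demonstrate the *mechanism*
and *direction* of the leakage bias and the internal correctness of every
stage; they do not predict the bias magnitude on any particular real
dataset. The CSV loader accepts real feature tables for that purpose.

## Preprocessing is deliberately leaky — and that is the point

`preprocess()` imputes column means and z-scores the **whole dataset before
cross-validation**. For real modeling this is mildly wrong (normalization
should be nested too); here it is a deliberate protocol choice: both steps
are outcome-free, so their leakage is small and identical across schemes,
whereas nesting them would entangle their (tiny) effect with the
feature-selection leak under study. The measured bias is therefore a lower
bound in this specific sense. The nested variant is intentionally not
offered. Numerical conventions: population (divide-by-N) standard
deviation, the common machine-learning scaler convention; constant columns
map to all-zeros and are flagged rather than dropped, so column indices
agree between schemes, and scorers give such columns the minimal score.

## The seven selectors

All seven are *filters*: they produce a score (or explicit ranking) per
feature, and `select_top_k()` keeps the k best with deterministic
tie-breaking by ascending column index, k ∈ {1, 2, 4, 8, 16, 32}, capped at
d with a warning. Per-method conventions, chosen where the procedure is
silent and fixed once:

* **t-score** — absolute Welch two-sample t (unequal variances); robust to
  class-conditional variance differences.
* **F-score** — one-way ANOVA F; for two groups this equals the squared
  pooled t, which the tests exploit as an independent oracle.
* **MIM** — plug-in mutual information in nats between the outcome and the
  feature cut into 10 equal-frequency bins. Rank-based binning buys
  invariance to monotone feature transforms; the plug-in estimator's
  positive bias (~(bins−1)/2N nats) is irrelevant for ranking since it is
  shared across features.
* **ReliefF** — Manhattan distance on range-normalized features, 10 nearest
  hits and misses, every sample an anchor (deterministic; anchor
  subsampling is available but off by default).
* **mRMR** — greedy difference criterion: MIM relevance minus mean absolute
  Pearson correlation with the already-picked set; the first pick is the
  relevance maximizer. The bootstrap-ensemble variant of mRMR is out of
  scope; the classic greedy criterion is implemented and labeled as such.
* **LASSO** — L1 logistic path over a geometric penalty grid from the
  all-zero penalty down by 10^-3 over 60 steps (glmnet); features ranked by
  entry step, ties by final |coefficient|, never-active features last. A
  fixed-penalty variant would need a per-dataset tuning loop, which the
  protocol does not include; the entry-order ranking is tuning-free.
* **SVM-RFE** — linear SVM (C = 1), rank by squared weight, drop the worst
  half while more than 64 features survive, then one per iteration. The
  halving phase keeps the cost near-linear in d; switching to single
  elimination at 64 (twice the largest k) protects the resolution of the
  ranking where it matters.

## Classifiers

Seven classifiers sit behind one fit/predict-probability contract; pooled
metrics need probabilities, so every model emits them (the RBF-SVM through
its internal calibration — pooling raw margins would make AUC-PR and
accuracy incomparable across classifiers). The grids are deliberately
small — a handful of values per classifier (`foldleak:::default_grids()`),
consistent with a protocol that tunes only a few hyperparameters; naive
Bayes has none, and the constant-majority baseline (ties predict class 0)
has none and ignores the features, which makes it provably scheme-invariant
— the experiment's internal negative control. Classifier seeds are derived
by hashing (experiment seed, fold index, config), so reruns are bitwise
stable and no global RNG state is consumed.

## Evaluation and inference

* **AUC-ROC** by the rank (Mann–Whitney) formula, ties counted 1/2.
* **AUC-PR** by the step-wise average-precision rule over descending unique
  thresholds — the trapezoid would interpolate optimistically. This is the
  quantity some radiomics papers call "AUC-F1".
* **Accuracy and confusion metrics** at a fixed 0.5 probability threshold;
  precision of an empty positive set is defined as 0.
* **Paired bootstrap** — N cases resampled with replacement; the metric
  difference is recomputed on both prediction vectors under the same draw;
  two-sided p = 2·min(tail fractions), clipped to [2/n_boot, 1]; 2000
  repeats by default; single-class resamples are redrawn. Identical inputs
  give p = 1 exactly. The paired percentile-tail form is one of several
  defensible bootstrap constructions; it is named in the output metadata so
  downstream users know which was used. p-values are reported raw, one per
  dataset, without multiplicity adjustment.
* **Dimensionality regression** — OLS of bias on N/d with the Pearson
  correlation and its t-based p-value; requires ≥ 3 datasets and
  non-constant N/d.

## Problem sizes and numerical choices

The analysis drivers and the acceptance script use N = 100 with d up to
2000 and 10–20 seeds per condition, and n_boot = 500 for calibration loops
— sizes at which every run completes in seconds to a few minutes on one
core while leaving the Monte-Carlo error well inside the asserted margins.
Degenerate cases are all given fixed conventions rather than errors where a
convention exists: infinite t/F statistics are capped one rank above the
largest finite score; k > d is capped at d; exact score ties break by
column index; best-model ties break by grid enumeration order.

## Known limitations

* The block-normal generator is a deliberate simplification; it supports
  mechanism-level conclusions, not magnitude predictions for real data.
* Only tenfold CV is implemented; how the bias changes under fivefold or
  leave-one-out CV is an open question the package does not answer.
* The LASSO and mRMR variants are the tuning-free/classic forms described
  above, not the only possible readings of those method names.
* No class rebalancing, outlier removal or calibration analysis — all
  excluded from the protocol so the selection leak remains the only
  difference between schemes.
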