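---
title: "Methods: late-fusion multi-omics classification of alcohol-associated liver disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: late-fusion multi-omics classification of alcohol-associated liver disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicstack)
```

## The problem

Alcohol-associated hepatitis (AH) and alcohol-associated cirrhosis (AC) present
similarly but are managed very differently, and separating either from healthy
controls (CT) without a biopsy is an open problem. `omicstack` implements a
three-class classification and biomarker-panel workflow that combines bulk
transcriptomic counts and proteomic intensities measured on partially
overlapping participants: some participants contribute a sample to both
platforms ("matched"), others to only one ("unmatched"). The central
statistical obstacle is scale: thousands of features against tens of samples
per class, which makes both overfitting and selection bias the dominant
failure modes. Every design choice below exists to keep the reported accuracy
an honest estimate at that sample size.

## Workflow overview

The analysis is organised in three stages, reproduced by `run_protocol()`:

1. **Stage 1 — per-omics classification.** Each platform's full dataset is
   classified independently with nested cross-validation (NCV) over a grid of
   pipeline configurations (feature-selection method and size, imputation
   strategy, classifier, hyperparameters).
2. **Stage 2 — integration.** (A) NCV on the *unmatched-balanced* subsets
   picks a winning configuration per omics; (B) those winners are refit on the
   entirety of the unmatched-balanced data and tested on the
   *matched-balanced* subsets; (C) the two base models' class probabilities on
   matched participants are concatenated into six meta-features
   (3 classes × 2 omics) and a logistic meta-classifier is cross-validated on
   them, against single-omics references on the same folds.
3. **Stage 3 — intersection.** The winning gene and protein panels are matched
   through a gene–protein identifier map (direct coding relations and
   same-family "familial" relations), and the observed number of shared pairs
   is compared with the exact expectation under uniformly random panels drawn
   from the significant feature sets.

Training on unmatched samples and stacking on matched ones keeps the two
stages disjoint: no matched-balanced label is read before Stage 2B, and the
meta-classifier only ever sees the six probabilities, never raw features, so
neither platform can dominate through its feature scale.

## Sample partitioning

A sample is *matched* when its participant contributed a sample to the other
platform in the same tissue (`split_by_matching()`). Because some per-class
unmatched pools are too small to train on, `rebalance()` moves whole matched
participants — both of their samples together — into the unmatched pool until
each class holds at least `min_unmatched_per_class` samples per omics (default
7, the smallest workable class in the motivating study's census). The movers
are drawn by seeded sampling within each class; the historical study's exact
moves are not recoverable, so the testable content is conservation, which
holds by construction and is verified by `verify_conservation()`:
per class and omics, `full = matched_balanced + unmatched_balanced`. The
motivating study's census ships with the package
(`ald_matching_counts()`) and passes both conservation identities exactly.

## Preprocessing

* **Outlier features** (transcriptomic): a feature is removed when its largest
  observed value exceeds `dominance_ratio` (default 10) times its
  second-largest — a one-parameter rule for "a single sample drives this
  feature". It needs at least three samples to be meaningful and refuses
  otherwise.
* **Missingness filtering and imputation** (proteomic): a protein is imputable
  only if *less than* `threshold_pct`% of samples are missing (grid 0/5/10%);
  at or above the threshold it is removed, and at threshold 0 every protein
  with any missing value is removed (the no-imputation arm). Imputation is
  `median` (per-protein median of observed values) or `zero` (sensible when
  missingness means below detection limit). Observed values are never altered
  and the operation is idempotent. When a pipeline is fit, the surviving
  feature list and the training medians are frozen into the model and reused
  verbatim on held-out or external data.

## Feature selection

Two filter rankings are available:

* **DE** — a per-feature Kruskal–Wallis test across the three classes with
  the tie-corrected chi-square approximation, Benjamini–Hochberg q-values,
  a `q ≤ q_threshold` gate (default 0.05) and rank by ascending p. The
  statistic is computed vectorized across features (row ranks, group sums,
  run-length tie correction) and agrees with `stats::kruskal.test` to
  1e-12 per feature. A rank test was chosen as a distribution-free engine
  that treats counts and log-intensities uniformly.
* **IG** — information gain in bits over equal-frequency quantile bins
  (default 3), computed per feature; a constant feature scores 0 and IG never
  exceeds the label entropy. Used for transcriptomic data.

An important small-sample fact, surfaced by the tests: with three classes of
five or fewer samples, the smallest achievable Kruskal–Wallis p-value times
thousands of features cannot clear a BH q ≤ 0.05 gate, so gated DE selection
legitimately returns nothing ("shortfall"); configurations that shortfall to
zero features are skipped with a warning rather than padded. Protocol runs on
small cohorts therefore default to IG for transcriptomics and ungated
(`q_threshold = 1`, rank-by-p) DE for proteomics, while the gate remains the
default of `selection_config()` and is exercised wherever the design is large
enough to support it. Ties in any ranking break lexicographically by feature
id, which makes selections reproducible.

## Nested cross-validation

`run_nested_cv()` re-runs preprocessing and feature selection inside **every**
training split: each outer training set (for the model that is scored on the
outer test fold) and each inner training split (for hyperparameter choice).
Selecting features once on all data and then cross-validating — the classic
leakage mistake — is implemented deliberately as `run_leaky_cv()` so the bias
is measurable: on null cohorts (no planted effect) the nested estimate sits at
chance (1/3) while the leaky estimate exceeds it by far more than 0.1.

Defaults are 5 outer and 3 inner stratified folds, feasible at per-class sizes
as small as the motivating study's (three per class); `make_stratified_folds()`
reduces `k` with a warning when a class is smaller than `k`. Classifier grids
are small by design for small n: kNN neighbours {3, 5, 7}, logistic-regression
inverse regularization C ∈ {0.01, 0.1, 1, 10}, SVM cost ∈ {0.1, 1, 10}.

## Classifiers

All classifiers consume features standardized by training mean/SD (an SD of 0
maps to 1), with the statistics frozen for prediction:

* **LR** — multinomial logistic regression via `nnet::multinom` with L2 weight
  decay `1/C`. The optimizer's random weight initialization is wrapped in a
  seed guard so fits are deterministic regardless of caller RNG state.
* **SVM** — three one-vs-rest binary `e1071::svm` machines (linear or RBF).
  Probabilities are a softmax over the three oriented one-vs-rest decision
  margins: deterministic and free of the extra cross-validation that Platt
  scaling would spend at this n.
* **kNN** — probabilities are neighbour class fractions; distance ties break
  by sample order, deterministically.

Integration-stage base models are restricted to LR and linear SVM, whose
coefficients are interpretable; the meta-classifier is LR with default
hyperparameters (C = 1). Feature importance for linear models is the mean
absolute coefficient across the three one-vs-rest class vectors on the
standardized scale (for LR, the full-class coefficient matrix is column-centred
first so the per-class vectors are symmetric).

## Candidate selection and relevancy

Each configuration's NCV result is a candidate: its outer accuracy, its panel
(feature selection re-run on all data; per-fold lists and a majority-vote
consensus are also kept), and a relevancy score. Relevancy is made explicit
and local: one-sided hypergeometric over-representation of the panel against
user-supplied term sets (GMT), BH-corrected, scored as the number of terms
with q ≤ 0.05. `select_best_candidate()` is a total lexicographic order:
accuracy (desc), then — proteomic only — imputation amount (asc; none and
threshold 0 count as least), then relevancy (desc), then panel size (asc),
then config id. The informal published criterion "maximize performance and
relevancy while minimizing size, preferring least imputation" is thereby made
deterministic; the priority order is this package's declared resolution.

## Intersection statistics

For panels of `k_g` genes and `k_p` proteins drawn uniformly without
replacement from significant sets of sizes `G` and `P` containing `M` mapped
pairs, each pair lands in both panels with probability `(k_g/G)(k_p/P)`;
linearity of expectation gives `E[shared] = M k_g k_p / (G P)`, computed
exactly by `expected_shared()` and validated against the Monte-Carlo oracle
`monte_carlo_shared()` rather than against any published value, since the
published significant-set sizes are not available.

## The synthetic cohort generator

`generate_cohort()` produces the structure the analysis assumes, so every
stage is testable without any download:

* counts are negative-binomial with per-gene baselines spread log-normally
  (sd 1 on log2) around `base_mean` and dispersion `nb_dispersion`
  (default 0.3, a typical bulk RNA-seq value);
* protein log2-intensities are Gaussian with per-protein baselines around
  `14 + log2(base_mean)` (≈ 20, a typical quantified-intensity scale) and
  noise `prot_sd` (default 1);
* each planted feature is shifted by `effect_log2fc` (default 2) in one
  affected class, cycling AH → CT → AC so the signal is genuinely three-way;
* missingness is MCAR at `mcar_rate` plus MNAR dropout logistic in intensity,
  `plogis(s·(q10 − x))` with the intercept pinned at the 10th percentile, so
  low-abundance values drop out first — the hallmark of proteomic data;
  `s = 0` disables MNAR exactly;
* a gene–protein map links planted features (every fifth pair `familial`,
  the rest `direct`), and one `signal_term` annotation over-samples planted
  features against uniform background terms.

Fixed seeds give bit-identical bundles. The generator emulates class
structure, partial matching, platform noise and dropout; it does **not**
emulate library-size variation, batch effects, correlated co-expression
modules, or demographic confounding. Passing tests therefore demonstrate that
the machinery is calibrated and leak-free under the stated generative model,
not that any particular accuracy will transfer to real cohorts — the published
cohort's headline accuracies are deliberately not reproduction targets here.

The defaults above are the package's study conditions. Where the motivating
work states no value (effect sizes, dispersions, noise), the defaults were
chosen once as field-typical and are exposed in `cohort_params()`.

## Numerical choices and degenerate inputs

* A feature with all values tied gets Kruskal–Wallis statistic 0 and p = 1
  (the tie correction would otherwise divide by zero).
* BH is the step-up `q_(i) = min_{j≥i} m·p_(j)/j`, clipped at 1, tie-stable.
* Micro-averaged one-vs-rest ROC pools all (sample, class) indicator /
  probability pairs, groups ties at equal thresholds, and integrates by
  trapezoid; it equals pairwise concordance with ties counted ½ to 1e-10.
* `rebalance` caps moves at the available matched pool; conservation holds for
  every input.
* External validation refuses when fewer than half the selected features are
  present; in opt-in intersection mode, absent features are reported and
  filled at their training means (0 after standardization), which leaves the
  frozen linear model applicable without refitting.
* All randomness flows through explicit seeds; stochastic fits restore the
  caller's RNG state.

## Problem sizes used by the shipped checks

The calibration suites run at desk scale, chosen as the smallest sizes at
which the properties under test are sharp: null calibration and leakage use 20
cohorts of 10 samples per class × 2000 genes; feature recovery uses 20 cohorts
of 20 per class with 100 planted genes at |log2FC| = 2; integration gain uses
50 replicates of 20 participants per class; the protocol demonstration uses
15 participants per class × 300 genes × 150 proteins.

## Known limitations

* The DE engine is a rank test, not a count model; at very small n its
  discreteness interacts with the BH gate as described above. Moderated or
  NB-GLM engines are out of scope by design.
* The relevancy criterion replaces curated judgement with a counted
  enrichment score; different term collections will rank candidates
  differently.
* The expected-shared formula conditions on the significant sets and the map;
  it does not model correlation between the two platforms' selections.
* Stage 2C freezes the base models from Stage 2B rather than refitting them
  per meta-fold; the alternative (per-fold base refits) would cost most of the
  matched data at these sizes.
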