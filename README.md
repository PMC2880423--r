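# aucbench

Honest performance estimation for gene-expression classifiers.

## The problem

Transcriptomic predictors of clinical endpoints (receptor status, response
to chemotherapy) are built from a few dozen to a few hundred samples over
tens of thousands of features. In that regime the estimated accuracy of a
classifier depends as much on *how* it is estimated as on the classifier
itself: feature selection tuned outside the resampling loop leaks
information, repeated cross-validation measures performance at 80% of the
sample size, and a single train/validation split confounds classifier
instability with test-set noise. `aucbench` is for biostatisticians and
computational biologists who want to benchmark classifier pipelines — or
plan sample sizes — with estimators that keep these effects separated.

It implements, as one tested package:

* **Difficulty scoring** — per-feature Fisher scores
  f_i = (μ₁ᵢ − μ₂ᵢ)² / (σ₁ᵢ² + σ₂ᵢ²), scaled cumulative-information curves
  F_k = Σ_{i≤k} f_(i) against k/N, and permutation significance with BH
  correction.
* **Five univariate feature-selection rules** — |Welch t| (FS1), with greedy
  correlation filtering at |r| > 0.75 (FS2), with meta-feature averaging of
  correlated features (FS3), BSS/WSS (FS4), |mean difference| (FS5).
* **Eight fixed-hyperparameter classifiers** — LDA, DLDA, QDA, logistic
  regression, KNN (k = 3, 11), RBF-SVM (γ = 0.5, 2.0; C = 10) behind one
  train/score contract emitting continuous scores oriented toward the
  positive class.
* **Nested two-level resampling** — the feature count j is tuned by
  5×-repeated stratified 5-fold CV strictly inside every outer training
  view; outer estimators are stratified 10×5-CV and the leave-pair-out
  (LPO) bootstrap, in which each (positive, negative) case pair is scored
  only by classifiers trained on bootstrap resamples containing neither
  case. The LPO standard error uses the delta-method-after-bootstrap
  (infinitesimal jackknife) plus a pair-level U-statistic term, so its CI
  reflects both finite-training and finite-testing variability.
* **Validation analysis** — conditional AUC (one model, fixed validation
  set), mean validation AUC over bootstrap-resampled training sets, a
  training/testing variance decomposition, and an RMSE comparison of the
  internal estimators against validation performance.
* **Learning curves** — AUC at increasing training sizes with the full
  pipeline re-run per subsample, fitted by Y = a + b/n (a = projected
  plateau; two-sided t test of the slope).
* **Congruence** — Fleiss/Cohen kappa agreement of the 0/1 selection
  matrices of different rules and hypergeometric gene-set enrichment (GMT).
* **A synthetic generator** with three preset difficulty tiers (easy /
  moderate / hard) whose Bayes AUC Φ(√(δᵀΣ⁻¹δ)/√2) is known in closed
  form, so every estimator can be validated against ground truth.

## Worked example

Evaluate the Welch-t + diagonal-LDA pipeline on the moderate synthetic tier
(130 training samples, 250 informative features among 10,000, prevalence
0.25):

```r
library(aucbench)
world <- generate_dataset(preset_profiles()$moderate, seed = 42)
grid  <- as.integer(seq(2, 41, by = 3))
outer_cv_10x5(world$train, "FS1", "DLDA", grid, seed = 42)
lpo_bootstrap(world$train, "FS1", "DLDA", grid, B = 200, seed = 42)
cond <- conditional_validation(world$train, world$validation,
                               "FS1", "DLDA", grid, seed = 42)
```

```
<CV10x5> AUC = 0.9991, SEM = 0.0009, 95% CI [0.9974, 1.0008]
<LPO>    AUC = 0.9967, SEM = 0.0050, 95% CI [0.9870, 1.0065]
conditional validation AUC: 1.0000 (j* = 41)
Bayes AUC of this world: 1.0000
```

Both internal estimators sit within their CIs of the validation AUC, and
the LPO interval is wider because it also carries the finite-training
component; the inner loop settled on j* = 41 features. With this world's
many moderately strong features the Bayes ceiling is effectively 1, so the
interesting quantity is not the AUC itself but how faithfully the internal
estimates track the validation set — which is what the RMSE analysis in
`analysis/04_factorial_benchmark.R` quantifies across all tiers.

## Analysis workflow

The `analysis/` scripts run the full study over the synthetic tiers, each
writing its tables under `results/`:

| script | what it does |
|---|---|
| `01_cohort_tables.R` | contingency tests on the published training/validation cohort tables |
| `02_simulate_worlds.R` | generates the three tiers, records ground truth (matrices to `scratch/`) |
| `03_difficulty.R` | Fisher scores, cumulative-information curves, permutation-significant counts |
| `04_factorial_benchmark.R` | FS × classifier grid, both estimators, validation RMSE (`--full` for the 5×8 grid at B = 5000) |
| `05_learning_curves.R` | inverse-size learning curves per tier |
| `06_congruence.R` | kappa agreement across selection rules, gene-set enrichment |

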