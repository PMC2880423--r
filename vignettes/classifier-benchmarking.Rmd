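---
title: "Honest evaluation of gene-expression classifiers across difficulty levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Honest evaluation of gene-expression classifiers across difficulty levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aucbench)
```

## The problem

Microarray-era transcriptomic classifiers promise to predict clinical
endpoints — receptor status, response to chemotherapy — from a single
expression profile. How well such a predictor will really work depends far
less on the choice of feature-selection rule or classification algorithm
than on two quantities that are easy to underestimate: how much class
information the feature space carries (the *difficulty* of the endpoint) and
how many training samples are available. `aucbench` implements the full
machinery needed to study that interplay honestly: difficulty scoring, five
univariate selection rules, eight fixed-hyperparameter classifiers, nested
resampling that never leaks test information into model choices, two
internal AUC estimators with standard errors, validation-set variance
decomposition, inverse-size learning curves, and feature-set congruence
statistics — all exercised end-to-end on a synthetic generator with known
ground truth.

## The data model and the synthetic worlds

All operations act on an `expression_dataset`: an $n \times p$ matrix of
expression values (samples by features, assumed already on the modeling
scale) with a binary endpoint label per sample, positive class coded 1.

The generator (`generate_dataset()`) draws class-conditional multivariate
Gaussian data with unit within-class SD. Informative feature $i$ is shifted
by $\delta_i$ (in SD units) in the positive class; optional feature blocks
share a common latent factor giving pairwise correlation $\rho$ within the
block. With equal class covariances the optimal attainable performance is
known in closed form,
$\mathrm{AUC}_{Bayes} = \Phi\!\left(\sqrt{\delta^\top \Sigma^{-1} \delta}/\sqrt{2}\right)$,
which every downstream estimator can be checked against. The validation
split is drawn from the same distribution: the benchmark deliberately
contains no batch effect, so a gap between internal estimates and validation
performance can only come from the estimators themselves.

`preset_profiles()` fixes three worlds emulating the canonical three-tier
design — an easy endpoint (ER-status-like), a moderate one (pCR-like) and a
hard one (pCR-within-ER-negative-like):

| tier | n train / validation | prevalence | informative / p | $\delta$ spectrum |
|------|----------------------|------------|------------------|-------------------|
| easy | 130 / 100 | 0.38 | 1500 / 10000 | $0.75 + 2.25u^4$ (top-heavy, max 3.0) |
| moderate | 130 / 100 | 0.25 | 250 / 10000 | linear 1.15 → 0.85 |
| hard | 50 / 40 | 0.54 | 5 / 10000 | linear 1.5 → 1.1 |

Three design choices deserve explanation.

* **A common array size.** All tiers share $p = 10{,}000$ features (a
  scaled-down array; a real U133A-class chip has ~22k probe sets). The
  scaled cumulative-information curve that ranks problem difficulty divides
  by the *total* score mass, most of which is the noise floor common to all
  endpoints measured on one platform. With tier-specific $p$ the curves
  order by informative *fraction* rather than informative *content* and the
  easy tier can paradoxically rank below the moderate one; a shared feature
  space restores the mechanism that makes the curves comparable.
* **Spectra calibrated to significant-feature counts.** The target the
  presets are calibrated to is the number of features a 10,000-permutation
  test calls significant at the operating threshold $P < 10^{-4}$: roughly
  1500 / 250 / 5 across the tiers. At these sample sizes that forces most
  informative effects above $\delta \approx 0.8$ (a weaker feature is never
  permutation-significant), so the hard tier is hard not because its five
  features are weak but because five features at $n = 50$ leave selection
  and fitting dominated by noise — which matches how the difficult endpoint
  behaves in practice. Calibration runs land at ≈1140 / ≈180 / median 4,
  within ±30% of the targets.
* **Blocks among informative features first.** Correlated blocks
  ($\rho = 0.85$) are laid down over informative features so that the
  correlation-filtering and meta-feature rules (FS2/FS3) have real work to
  do; a world with independent features makes them degenerate into FS1.

What the generator does **not** emulate: heavy-tailed intensity
distributions, probe-level artifacts, batch effects, or label noise.
Passing tests on these worlds therefore demonstrate correctness of the
estimators and pipelines, not robustness to those real-data pathologies.

## Difficulty scoring

`fisher_scores()` computes, per feature,
$f_i = (\mu_{1i} - \mu_{2i})^2 / (\sigma_{1i}^2 + \sigma_{2i}^2)$ with
$n-1$-denominator sample SDs (matching the unequal-variance t convention
used by FS1; under the generator $E[f_i] \to \delta_i^2/2$). Features
constant in both classes score 0 with a warning — they carry no class
information and real filtered data do contain them.

`cumulative_information()` sorts the scores decreasingly, accumulates
$F_k = \sum_{i \le k} f_{(i)}$, scales the curve to maximum 1 and plots it
against $k/N$ so that endpoints with different sample sizes are comparable;
easier problems rise faster.

`permutation_significance()` recomputes all scores under label permutations
(vectorized as two matrix products per chunk) and reports add-one p-values
$p = (1 + \#\{f^{perm} \ge f^{obs}\})/(1 + n_{perm})$, which are never 0 and
remain BH-compatible. At the conventional operating threshold $10^{-4}$ with
10,000 permutations only features whose observed score beats *every*
permutation qualify; no BH-adjusted q can reach that threshold on an
array-sized feature set, so the reported significant count applies the
threshold to the raw p (the BH q is also returned for any other use).

## Feature selection without leakage

The five rules: FS1 ranks by |Welch t|; FS2 additionally walks down the
ranking greedily dropping any feature whose Pearson |r| with an
already-retained feature exceeds 0.75; FS3 performs the same walk but merges
each dropped feature into the retained feature it correlates with, averaging
their values into a meta-feature whose t score is then recomputed; FS4 ranks
by BSS/WSS; FS5 by |mean difference|. Choices the definitions leave open,
fixed here once:

* ties in any criterion break by ascending feature index (determinism across
  platforms and BLAS builds);
* a dropped feature attaches to the *highest-ranked* retained feature it
  exceeds the threshold with;
* meta-feature averaging is unweighted on the raw values;
* the filter is applied lazily — the walk stops once the requested top-$j$
  exists, which provably yields the same top-$j$ as filtering the whole
  list;
* correlations and rankings are always computed on the training view of the
  current resampling iteration, never on held-out rows (a mutation test
  perturbs held-out samples and asserts bit-identical rankings, tuned
  feature counts and fitted parameters).

## Classifiers

Eight fixed-hyperparameter algorithms behind one train/score contract that
always emits continuous scores oriented so larger favors the positive class
(AUC needs nothing else): LDA, DLDA and QDA as Gaussian discriminants
(posterior log-odds), logistic regression (linear predictor), KNN with
$k = 3$ and $k = 11$ (fraction of positive neighbors; distance ties broken
by training-sample order), and RBF-kernel SVMs with $\gamma = 0.5$ and
$2.0$ at cost $C = 10$ (signed decision value, orientation checked on the
training labels). Hyperparameters are deliberately frozen: tuning them would
have to live inside the inner resampling loop to avoid optimization bias.

Numerical choices: KNN and SVM standardize features by training mean/SD
(distance and kernel methods are scale-sensitive); discriminant and
logistic models see raw values. Singular covariances get an escalating
ridge on the Cholesky factorization. QDA requires per-class $n > j$
(otherwise an error) and, in the narrow band $j < n_c < j + 2$, shrinks the
deficient class's covariance to the pooled one. Logistic fits cap at 50
IRLS iterations and keep the last iterate under separation.

## Performance estimation

`auc_wmw()` is the Wilcoxon–Mann–Whitney statistic: the average over all
(positive, negative) pairs of the kernel $[s_p > s_n] + \tfrac12[s_p = s_n]$.

**Inner loop** (`inner_select_j()`): the number of features $j$ is the only
tuned parameter. Five-times-repeated stratified 5-fold CV inside the current
training view re-ranks features on each fold-training part, trains on the
top $j$, scores the left-out fold, and averages fold AUCs per $j$ (averaging
per-fold AUCs, not pooling scores, keeps folds exchangeable); $j^*$
maximizes the average, ties resolving to the smallest $j$ — the less
overfit model.

**Outer estimators.** `outer_cv_10x5()` runs ten repeats of stratified
5-fold CV, the full inner pipeline re-running inside every fold; the
estimate is the grand mean of the 50 fold AUCs, the SEM averages the ten
per-repeat $SD/\sqrt 5$ values, and the CI is $\pm 1.96\,$SEM. Fold splits
are a deterministic function of the seed, so every model evaluated under
one master seed reuses identical splits and model comparisons are not
confounded with split noise.

`lpo_bootstrap()` draws $B$ stratified bootstrap training sets (class
counts preserved), runs the full pipeline on each, and evaluates every
(positive, negative) case pair only on replicates containing *neither*
case, averaging the WMW kernel per pair and then over pairs. This estimates
the mean AUC over training sets of size $n$ — exactly the quantity a fixed
validation set measures in expectation — rather than the $0.8n$-training
performance CV estimates. Its SEM uses the delta-method-after-bootstrap in
the infinitesimal-jackknife form: per case $i$,
$\hat C_i = \mathrm{cov}_b(N_{bi}, \hat A_b)$ between the case's inclusion
count and the replicate's pair-averaged performance, giving a training
component $\sum_i \hat C_i^2$, plus a finite-test component from the
two-sample U-statistic variance of the pair-averaged kernel matrix. The
original influence-function derivation is not reprinted in the literature
this construction follows; it is isolated behind this one function and
validated empirically against Monte-Carlo variance over independently drawn
training sets. Pairs never jointly out-of-bag are dropped with a message
(negligible for $B \gtrsim 200$); if most pairs are uncovered the function
stops and advises a larger $B$.

**Validation.** `conditional_validation()` trains once on the full training
set (tuning strictly inside it) and scores the fixed validation set — the
performance *conditional* on this particular training set.
`mean_validation()` bootstraps the training set, yielding the mean
validation AUC together with a variance decomposition: `var_train`, the
variance of the conditional AUCs (classifier instability under training
resampling), and `var_test`, the U-statistic variance at the averaged pair
kernel (finite validation set). `rmse_compare()` summarizes, over a model
grid, how far each internal estimator sits from the mean validation AUC.

## Learning curves

`subsample_performance()` evaluates a model at increasing training sizes:
per size, ten independent stratified subsamples, each assessed by a single
stratified 5-fold CV with the entire pipeline re-run per fold.
`fit_learning_curve()` then fits $Y = a + b/n$ by OLS *on the replicate
AUCs*, not the size means — the within-size spread is what gives the slope
t-test its residual degrees of freedom, which is the only way a slope
p-value is obtainable from ~10 sizes. $a$ is the projected asymptote
$Y(\infty)$; noise-free points on a true inverse-size curve are recovered
exactly.

## Congruence

`build_selection_matrix()` encodes each rule's top-$j^*$ selection as a 0/1
column over the whole feature universe (meta-features expand to their
constituents; the universe is the full array, matching the no-prefiltering
convention — expected-agreement terms depend on this choice).
`kappa_congruence()` reports Fleiss' multi-rater kappa plus all pairwise
Cohen kappas: with five "learners" the multi-rater form is the natural
summary, but the pairwise matrix is emitted so either reading is available.
Columns constant over the universe make kappa undefined; such pairs are
flagged and excluded from the pairwise mean. `hypergeometric_enrichment()`
maps a selection to gene sets by the upper-tail hypergeometric p, ranks by
raw p (reporting the top $n$ = selection size), and adds a BH column for
modern use.

## Reproducibility and problem sizes

Every stochastic operation derives a child seed from (master seed,
operation name, iteration index), so results are bit-reproducible and
independent of execution order, and identical splits are shared across
models by construction. The compiled fast path for the
univariate-ranking + DLDA pipeline computes each CV repeat's per-fold class
sums in one pass over the matrix; it is tested to agree with the plain-R
generic path to machine precision, so the two routes check each other.

The package's test suite and acceptance script run the full designs
(10×5 outer CV, 5×5 inner CV, 10,000 permutations) but scale the bootstrap
to $B = 100$–200 replicates and use holdout oracles of ~1000 samples;
these sizes were chosen once as the point where Monte-Carlo error is
comfortably below the tolerances being asserted. The paper-scale
$B = 5000$ is available throughout (`--full` in the factorial driver).

## Known limitations

* The Gaussian equal-covariance generator makes linear methods
  near-optimal; it cannot reveal regimes where QDA or kernel methods
  dominate.
* The Bayes AUC formula assumes equal class covariances; generated worlds
  satisfy this by construction, but the formula would not transfer to
  heteroscedastic extensions.
* The infinitesimal-jackknife SEM is an approximation whose small-$B$ bias
  is not corrected; it is validated against simulation at the $B$ used, not
  proven.
* Difficulty scoring assumes additive, independent feature contributions;
  strongly interacting features would be mis-ranked by any univariate
  score, and no multivariate difficulty measure is provided.
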