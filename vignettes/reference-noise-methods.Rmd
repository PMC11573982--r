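---
title: "Modelling clinical-reference uncertainty in radiomics classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling clinical-reference uncertainty in radiomics classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refnoise)
```

## The problem

Radiomics studies train classifiers on quantitative image features against a
clinical reference standard — here, a binary "clinically significant vs
non-significant" prostate cancer label derived from Gleason scoring. The
reference is usually treated as error-free, but biopsy subsampling, grading
disagreement and annotation errors all corrupt it. `refnoise` asks, by
simulation: *if some fraction of the training labels are wrong, how much do
feature selection and model performance actually degrade — and does the
apparent (training) performance tell you?*

The experiment is a full factorial over:

* **permutation level** — the fraction of training references inverted
  (0 to 50% in 5% steps, eleven levels);
* **repetition** — 20 independently seeded draws of the inverted subset per
  level;
* **pipeline** — four feature selectors (Mann-Whitney U at
  $\alpha = 0.05$, RFE, lasso, mRMR) crossed with two classifiers (random
  forest, lasso-penalized logistic regression);
* **evaluation surface** — the same out-of-fold scores judged against the
  permuted training labels (`train_vs_permuted`, what the analyst would see),
  against the true training labels (`train_vs_true`), and hold-out scores
  against true hold-out labels (`holdout_vs_true`).

Labels are only ever permuted in the 70% training partition; the 30%
hold-out set keeps its true references and never touches training.

## Balance-preserving label inversion

At level $L$ on $n$ training samples, exactly $k = \mathrm{round}(L\,n)$
labels are flipped (round-half-away-from-zero, the single rounding rule used
throughout the package). The flips are split $\lceil k/2 \rceil$ /
$\lfloor k/2 \rfloor$ between the two classes, the larger half going to the
majority class, and are drawn uniformly without replacement within class.
Prevalence therefore moves by at most $1/n$. When one class cannot supply
its quota (conceivable at 50% under strong imbalance) the remainder is
reassigned to the other class — a documented extension; the balance bound
then no longer applies. Every (level, repetition) cell derives its own seed
from the master seed via a stable arithmetic hash, so any cell is
reproducible in isolation.

## The synthetic data generator

Real radiomics tables cannot be bundled, so the generator emulates the two
dataset shapes studied: `profile_dataset1()` (260 samples x 265 features,
49% prevalence) and `profile_dataset2()` (100 x 7106, 80% prevalence — the
high-dimensional, imbalanced regime). The signal model is equal-variance
Gaussian: an informative feature differs between classes by a standardized
shift $d$, so its single-feature ROC AUC is $\Phi(d/\sqrt{2})$ — the
closed form used to calibrate the generator in tests. Informative features
sit in equicorrelated blocks (shared latent factor, within-block correlation
$\rho = 0.8$, blocks of 5) emulating redundant radiomics feature families,
which is what gives mRMR's redundancy penalty something to do. All other
features are label-independent Gaussian noise.

Defaults: 10 informative features for the Dataset-1 profile and 20 for
Dataset-2, $d = 1.5$ and $d = 1.0$ respectively. For the Dataset-1 profile
the block structure gives a Mahalanobis separation
$\Delta^2 = 2\,d^2\,m/(1-\rho+m\rho)$ with $m = 5$, so $d = 1.5$ puts the
Bayes AUC at $\Phi(\Delta/\sqrt 2) \approx 0.95$, matching the strong
level-0 models reported for the real dataset this profile emulates; $d = 1$
would cap the Bayes AUC near 0.86, noticeably below that regime.

What the generator does **not** emulate: the heavy-tailed and mixed-scale
marginal distributions of real radiomics features, non-Gaussian class
overlap, and feature-dependent (instance-dependent) label error. Passing
tests on synthetic data therefore validate the machinery and the
qualitative response to *symmetric, feature-independent* label noise; they
do not certify effect sizes on real data. Users with the real tables (the
two public prostate datasets, converted to the CSV layout) can rerun the
same pipeline via `experiment_config(dataset = list(features = ..., labels
= ...))`; with such data the level-0 training AUC should sit near the
originally reported 0.94 and fall toward ~0.58 at the 50% level — a useful
external integration check, not part of the test suite.

## Selectors and classifiers

* **Mann-Whitney U**: vectorized midrank statistic with tie-corrected
  normal approximation (no continuity correction); a feature is kept when
  its unadjusted two-sided p-value is below $\alpha = 0.05$. Constant
  features get $p = 1$.
* **RFE**: iterative elimination of the lowest-|coefficient| features under
  an L2-penalized logistic ranker on z-scored features (fixed ridge penalty
  $\lambda = 0.01$; a fixed penalty keeps the ranker defined for $p > n$
  and deterministic). While more than twice the target count survives,
  $\max(\text{step}, \lfloor p_{\text{now}}/50 \rfloor)$ features are
  dropped per round; then one at a time.
* **Lasso selection**: `glmnet` L1 logistic path, penalty chosen by
  stratified cross-validation on binomial deviance (`lambda.min`); features
  with nonzero coefficients are kept.
* **mRMR**: greedy forward selection under the MID (difference) criterion
  $I(f;y) - \overline{I(f;s)}$, with plug-in mutual information (natural
  log) on equal-frequency discretizations into $\lceil \sqrt n \rceil$
  bins; ties break by feature order. The difference form avoids the
  division-by-zero the quotient form hits on zero-redundancy steps.

RFE and mRMR select to a target of $\min(30, \lfloor n_{\text{train}}/5
\rfloor)$ features, capping model complexity relative to the sample size.
Every selector that comes up empty (nothing below $\alpha$; an
intercept-only lasso) returns *all* features with a `fallback_used` flag.
This fallback is part of the studied phenomenon: when heavy noise defeats a
selector in every repetition, all repetitions select identically and the
stability coefficient jumps to 1 — behaviour reported for lasso at the 45%
level in the original study.

Classifiers sit behind one interface: random forest (500 trees,
$\sqrt p$ candidate features per split) and lasso-logistic (inner
stratified 5-fold cross-validation on deviance, scored at `lambda.1se`).
`lambda.1se` — the strongest penalty within one standard error of the
deviance optimum — is used for *classification* because it is markedly more
robust to label noise than `lambda.min`; the looser `lambda.min` is kept
for *selection*, where sensitivity is the point. Scores are class-1
probabilities; the confusion cutoff defaults to 0.5 (any fixed cutoff works
for the degradation question; 0.5 is the reproducible convention).

## Cross-validation and the leakage question

Training uses stratified K-fold cross-validation on the permuted labels
(K = 10 when the training set has at least 150 samples, else 5, mirroring
the per-dataset choice in the motivating study). "Training performance" is
computed from pooled out-of-fold scores, not resubstitution.

Where feature selection happens relative to the folds is the one genuinely
open design point, and the package deliberately uses **both** placements:

* **Once per (permuted) training set, outside CV** — this is the unit the
  Jaccard stability statistic needs (one selected set per repetition), and
  it feeds the final model refit on the full training set, whose only job
  is hold-out scoring (hold-out samples never entered selection, so that
  surface is unbiased either way).
* **Re-run inside every fold, on the fold's training samples only** — this
  produces the out-of-fold scores. Selecting outside CV leaks the permuted
  labels of the evaluated fold into the feature set: on the Dataset-1
  profile at the 50% level that inflates the out-of-fold AUC against
  permuted labels to ~0.75 where the correct null value is 0.5. Per-fold
  selection restores the null exactly, at the cost of running each
  selector K times per cell.

## The noisy-AUC expectation

For scores whose AUC against true labels is $A$, evaluated against labels
flipped by the balance-preserving rule, the expected AUC has a closed form.
With per-class flip counts $k_+, k_-$, the noisy-positive group mixes true
positives and true negatives with weights $w_{pp}, w_{pn}$ (and the
noisy-negative group $w_{nn}, w_{np}$); comparing a random noisy-positive
against a random noisy-negative wins with probability $A$ on a true-(+,-)
pair, $1-A$ on the reversed pair, and $1/2$ within a class:

$$\mathbb{E}[\mathrm{AUC}] = w_{pp}w_{nn}A + w_{pn}w_{np}(1-A)
  + (w_{pp}w_{np} + w_{pn}w_{nn})\,\tfrac12 .$$

Ties are assumed negligible (continuous scores). `expected_noisy_auc()`
shares its flip-count arithmetic with `permute_reference()` so the two
cannot drift apart. The formula is validated against Monte-Carlo label
flipping on fixed scores in the test suite.

Two things the formula says, and the experiment reproduces: the curve
declines monotonically in the level for any informative scores, and reaches
exactly 0.5 at the 50% level under balanced flips. One thing it does *not*
model: it holds $A$ fixed at the level-0 value, i.e. it assumes training
itself is unharmed by the noise. In the full experiment the model's
true-label AUC does degrade with the training noise level, so the observed
`train_vs_permuted` curve runs systematically *below* the fixed-$A$
expectation in the mid-level range (deviations up to ~0.1 around levels
0.25-0.40 on the Dataset-1 profile), converging again at both ends where
the expectation is pinned. Substituting the *measured* per-level true-label
AUC into the same mixture reproduces the observed curve to ~0.02, which is
the package's evidence that the mixture arithmetic, as opposed to the
fixed-$A$ idealization, is correct.

## Statistics

Feature-selection stability at a level is the multi-set Jaccard similarity
across the 20 repetitions' selected sets: $|\cap_r S_r| / |\cup_r S_r|$,
1 when every repetition selected identically, 0 when no feature is common
to all; an empty union counts as 1 by convention. Metrics are compared
across levels per pipeline and surface with one-way fixed-effects ANOVA
(repetitions as replicates) and all-pairs t comparisons with Bonferroni
adjustment; a metric that is constant everywhere yields the vacuous
$F = 0$, $p = 1$ rather than `aov`'s `NaN`.

## Numerical and degenerate-input choices

* Count rounding: half away from zero, everywhere.
* Zero-variance features z-score to exactly 0 (scale guard), get
  Mann-Whitney $p = 1$, and are never selected on merit.
* `glmnet` paths are capped at 50 lambdas with `lambda.min.ratio = 0.01`;
  single-feature models are padded with an inert zero column (`glmnet`
  requires two).
* Fold counts silently never drop below 2 (outer) / 3 (inner); when the
  minority class is smaller than the requested fold count, K is reduced
  with a warning.
* Level-0 permutation cells are the identity, so the experiment computes
  the first repetition and replicates it — the other repetitions are the
  same computation by construction.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` exercise the Dataset-1 profile at
full scale (260 x 265, 11 levels x 20 repetitions) for the Mann-Whitney +
lasso-logistic pipeline, and the three multivariate selectors at levels 0
and 0.05 x 20 repetitions for the stability statistic; the Dataset-2
profile is exercised at reduced repetition counts for its qualitative
property (larger between-repetition spread than Dataset-1 at matched
levels). Selector-against-oracle checks run on purpose-built small designs
(exhaustive greedy mRMR at $p \le 8$; permutation-test Mann-Whitney at 15
per class; an orthogonalized design for the lasso soft-threshold set).

## Known limitations

* Symmetric, class-balanced, feature-independent noise only — by design,
  as in the motivating study; no instance-dependent or asymmetric error
  models.
* Binary outcomes only; no multi-class or time-to-event references.
* The fixed-$A$ expectation is a descriptive oracle for the shape of the
  degradation curve, not a bias correction.
* Supplementary parameter tables of the original study were not available;
  selector and classifier settings here are documented defaults, not
  reproductions.
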