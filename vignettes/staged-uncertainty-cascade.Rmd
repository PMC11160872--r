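---
title: "Uncertainty-gated staged risk prediction: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-gated staged risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagedrisk)
```

## The problem

Many clinical risk models face an asymmetry in data acquisition cost. A
first block of predictors — demographics, lifestyle, medical history — is
essentially free, while a second block, derived from imaging such as
DXA (dual-energy X-ray absorptiometry) scans of the hip, requires an
appointment, money and radiation exposure. The motivating application is
hip-fracture risk in middle-aged and older adults: clinical variables
alone discriminate poorly, imaging-derived features discriminate well,
and the clinical question is *who actually needs the scan*.

`stagedrisk` implements a staged (cascade) classifier for this setting:

1. **Stage 1** fits a bootstrap ensemble on the cheap block only. For each
   subject it produces a predicted probability $\mu_1$ (the mean of the
   $B$ base-model probabilities) and an uncertainty $s_1$ (their sample
   standard deviation).
2. **The deferral rule** retains the Stage-1 prediction when
   $s_1 \le \sigma^{*}$ **and** $|\mu_1 - 0.5| > h^{*}$ — i.e. the
   ensemble is both internally consistent and decisively far from the
   0.50 midpoint. Otherwise the subject cascades to
3. **Stage 2**, an ensemble fit on the cheap **and** expensive blocks
   together, whose mean probability becomes the final prediction.

Stage-2 predictions are computed *only* for cascaded subjects; the
fraction retained at Stage 1 is exactly the fraction of scans avoided.

## Uncertainty from bootstrap ensembles

Each ensemble draws $B$ bootstrap samples of $\mathrm{round}(f\,n)$
training rows (with replacement; a draw missing a class is redrawn) and
fits one base model per draw. The standard deviation of the $B$
predicted probabilities is the uncertainty signal. Its premise — tested
as a property in the suite — is that subjects near the decision boundary
receive more variable predictions across resamples than subjects with
extreme risk. Uncertainty here is *ensemble disagreement*, not a
calibrated posterior; the two thresholds are therefore tuned empirically
rather than interpreted probabilistically.

Base learners are pluggable (`base_learners()`): the default is a
closed-form ridge regression on the 0/1 labels with predictions clipped
to $[0,1]$ — a regularized linear classifier cheap enough to refit
thousands of times inside nested cross-validation — with penalized
logistic regression (`"glmnet"`) and gradient-boosted trees
(`"xgboost"`) as registered alternatives. Linear base learners report
$|\beta_j|$ as importance; trees report gain.

## Threshold tuning and the scaled weighted AUC

The pair $(\sigma^{*}, h^{*})$ is tuned by exhaustive grid search on a
validation set, maximizing the **scaled weighted AUC**

$$J = \frac{n_r\,\mathrm{AUC}_r + n_c\,\mathrm{AUC}_c}{n_r + n_c},$$

the size-weighted mean of the AUC among retained subjects and the AUC
among cascaded subjects. A subset with a single outcome class (or fewer
than two members) contributes its size with AUC taken as 0.5. This
definition is deliberately isolated behind `scaled_weighted_auc()` so it
can be swapped; the metric's name fixes neither the weighting nor the
degenerate-subset convention, and this is the package's concrete choice.

Ties are broken toward larger Stage-1 retention, then smaller
$\sigma^{*}$, then grid order — when the objective cannot distinguish
two gates, prefer the one that avoids more scans.

A consequence of the 0.5 fallback worth knowing: when Stage 1 is very
weak and Stage 2 very strong, a retained set of confident *negatives* is
a single-class subset scored 0.5, so the objective often prefers
cascading nearly everyone, and tuned retention can be far below the
fraction of subjects that are in fact classifiable from the cheap block.
The retention reported on such cohorts is honest about that dynamic;
alternative objectives (e.g. scoring retained subjects by accuracy, or
pooling before the AUC) would trade differently and can be swapped in
behind the same operation.

Tuning evaluates both stages' distributions on the whole validation set
once — the cost semantics (Stage 2 only for cascaded rows) apply to
deployment-time prediction in `staged_predict()`, not to tuning.

## Nested cross-validation

Evaluation uses stratified 10-fold outer cross-validation (on the
default 547-subject cohort: ~492-subject outer-training folds,
54–55-subject test folds). Within each outer-training fold, two
stratified 45-subject validation sets are carved out; ensembles (and the
whole feature pipeline) are fit on the remaining rows; validation set 1
tunes the thresholds; the outer test fold scores Ensemble 1, Ensemble 2
and the staged model. The second validation set plays no role in any
decision — it is carved and reported (`$validation2`) to keep the
training sample identical to a design that reserves it, and because a
second tuning stage (e.g. probability calibration) could later use it.
Across-fold averages and standard deviations form the headline report;
pooled outer-test predictions feed the DeLong and McNemar comparisons
(per-fold DeLong p-values are also emitted). A 10-fold scheme is used
rather than a single split so that the across-fold standard deviations
in the report are well-defined.

Everything that learns from data — centering/scaling, the
near-zero-variance and correlation filters, RFE, hyperparameter
selection, threshold tuning — is refit strictly inside each outer
training fold. The test suite includes a leakage canary: corrupting
held-out rows with outcome-correlated values must leave the fitted
ensemble bit-identical.

## Feature pipeline

Order: near-zero-variance filter → correlation filter →
centering/scaling with spatial sign → optional recursive feature
elimination. The order is fixed so each stage's preconditions hold: the
correlation filter requires no constant columns, and RFE should never
see a constant or duplicated feature.

* **NZV filter** (defaults `freq_ratio = 19`, `unique_pct = 10`, the
  caret convention): removes constants, and features dominated by one
  value *and* nearly unvarying.
* **Correlation filter** (default $|r| > 0.9$): greedy — repeatedly find
  the worst pair, drop the member with the larger mean absolute
  correlation to all other live columns, ties keep the lower column
  index. Deterministic given column order; the retained set provably
  contains no pair above the threshold.
* **Spatial sign**: after standardization each row is divided by its
  Euclidean norm, projecting subjects onto the unit sphere to blunt
  multivariate outliers. All-zero rows are left unchanged (the only
  choice that is both defined and deterministic).
* **RFE** (off by default): backward elimination driven by base-learner
  importance, removing `step` features per round, landing exactly on
  `n_target`; returns a full elimination-order ranking. Base estimator,
  step and target are configuration because no single choice is
  canonical; the default estimator is the same ridge learner the
  ensembles use.

## The synthetic cohort generator

Because the motivating cohort (a national-biobank DXA substudy) is
access-restricted, the generator reproduces its *structure*, not its
data: 547 subjects of whom exactly 94 are positive, a weakly informative
clinical block and a strongly informative, internally correlated
imaging block.

* Latent risk $z_i = b_i\,\beta_1 w_1^\top x_{1i} + \beta_2 w_2^\top
  x_{2i} + \varepsilon_i$; labels are assigned to the `n_positives`
  largest $z_i$ (exact-count thresholding rather than Bernoulli draws,
  so the 547/94 composition holds for every seed).
* The imaging block is equicorrelated via a single Gaussian factor with
  loading $\sqrt{\rho_2}$ — one parameter, closed-form checks.
* Defaults $\beta_1 = 0.25$, $\beta_2 = 2.5$, $\rho_2 = 0.5$,
  $\sigma_\varepsilon = 1$ were calibrated once against the oracle
  scores so the latent block AUCs (~0.57 clinical, ~0.95 imaging) match
  the weak-clinical / strong-imaging regime the method targets.
* A random 30% of subjects (`easy_fraction`) have their Stage-1 term
  inflated 3× so part of the cohort is genuinely classifiable from the
  cheap block — the subpopulation a deferral rule can save.
* The first three clinical features are 0/1 indicators (prevalences
  0.5/0.4/0.2) standing in for dummy-coded categoricals;
  `cohort_clinical_table()` re-expresses them as factors for the
  baseline-statistics machinery. No attempt is made to copy the real
  cohort's marginal distributions beyond the 547/94 split.

What passing tests on this generator do **not** show: robustness to
missing data, measurement error, covariate shift, non-linear
signal, or categorical structure richer than binary indicators — real
cohorts have all of these and the generator deliberately has none.

## Baseline statistics

`fisher_exact_p()`, `chi_square_p()` and `welch_t_p()` wrap the standard
tests (two-sided Fisher exact; Pearson chi-square with Yates continuity
correction by default; Welch t with Satterthwaite degrees of freedom
computed directly from group summary statistics). The Yates-corrected
variant is the default because the published per-level p-values for this
kind of table are consistent with the corrected statistic, and the
Welch form because group-summary tables of this kind are consistent
with the unequal-variance test; the uncorrected chi-square remains
available by flag. Multi-level categoricals are tested one level versus
rest, with an additional collapsed row for binary features. No
multiplicity correction is applied.

## Numerical conventions and degenerate inputs

* AUC is the Mann–Whitney statistic with ties counted ½ (rank-based);
  it errors on single-class inputs rather than guessing.
* The class-label cutoff for accuracy/sensitivity/specificity is fixed
  at 0.5, the same anchor the deferral rule uses; a single-class label
  vector yields a missing (not zero) sensitivity or specificity.
* DeLong: identical score vectors give p = 1 by convention; constant
  scores raise a degenerate-variance error; a perfect classifier yields
  a zero-width interval at 1 after truncation to $[0,1]$.
* McNemar: exact binomial below 25 discordant pairs, continuity-corrected
  chi-square otherwise; no discordance gives p = 1.
* Probabilities from the two stages are pooled into one ROC without
  cross-stage calibration. This is a known limitation: if the stages are
  differently calibrated, the pooled ranking mixes scales. The per-stage
  subset AUCs in the tuning trace are unaffected.
* Uncertainty is the *sample* standard deviation ($B = 1$ defined as 0);
  bootstrap draws are with replacement, which is what makes the ensemble
  a bootstrap.

## Problem sizes used by the test-suite simulations

The property and end-to-end tests run at deliberately modest sizes
chosen as the smallest at which the tendencies are stable: 20–25 seeds
for tendency checks, cohorts of 200–547 subjects, ensembles of 5–25
base models, 10 outer folds for the full-size runs and 3–4 for
structural smoke tests. The acceptance script runs the full 547-subject,
$B = 25$, 10-fold experiment once per invocation.

## Worked example

```{r example, eval = FALSE}
cohort <- generate_cohort(cohort_config(seed = 1))
res <- nested_cv(cohort,
                 cv = cv_config(seed = 101),
                 cfg1 = ensemble_config(n_base_models = 25, seed = 2),
                 cfg2 = ensemble_config(n_base_models = 25, seed = 3))
print(res)
glance(res)
autoplot(res)
```

## Known limitations

* The deferral rule uses a single halfway threshold applied
  symmetrically around 0.5; asymmetric costs (missing a fracture is
  worse than an unnecessary scan) would want two.
* No probability calibration within or across stages.
* The scaled-weighted-AUC objective with its 0.5 fallback can
  under-retain when Stage 1 is near-uninformative (see above).
* The generator's clinical block is far simpler than real
  questionnaire data; absolute metric values on it are not predictions
  of real-cohort performance, only the orderings and tendencies the
  tests assert.
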