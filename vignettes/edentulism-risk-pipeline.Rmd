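---
title: "Developing and validating a 12-year edentulism risk model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and validating a 12-year edentulism risk model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edentrisk)
```

## The problem

Edentulism — the loss of all natural permanent teeth — affects health,
nutrition and quality of life in older adults. Given a baseline interview of
a dentate adult over 50 (demographics, smoking, dental care use, income,
alcohol use, self-rated health, loneliness, and a 0–35 cognition score),
what is their probability of becoming edentulous over the following
12 years?

`edentrisk` implements the full model-development-and-validation workflow
for this question as used with Health and Retirement Study (HRS) cohort
data: a one-row-per-person table goes in; a validated logistic prediction
equation, its test-set discrimination with a bootstrap confidence interval,
and classification metrics come out. The HRS micro-data themselves are
access-restricted, so the package also ships a synthetic cohort generator
that emulates the analytic sample's published structure, making every stage
testable end to end.

## The model

The outcome is 12-year incidence: `Y = 1` if a participant dentate at
baseline reports complete tooth loss 12 years later. Risk is modelled by
plain maximum-likelihood logistic regression

$$\Pr(Y = 1 \mid x) = \frac{e^{L}}{1 + e^{L}}, \qquad
L = \beta_0 + \beta^\top x,$$

where `x` collects 0/1 indicators against fixed reference categories
(Caucasian, female, college-plus education, never smoker, dental visit
within 2 years, cognition score ≥ 23, drinks alcohol, good+ self-rated
health, not lonely, income $75k+) and age enters untransformed as
years / 10. The reference 7-variable equation shipped with the package
(`edentulism_equation()`) is

```
L = -4.866 + 0.472 R1 + 0.322 R2 - 0.130 R3 + 0.078 G + 0.158 A
    + 0.908 E0 + 0.646 E1 + 1.261 S0 + 0.389 S1 + 0.850 D + 0.599 C
```

so, for instance, current smokers carry `exp(1.261) = 3.53` times the
adjusted odds of never smokers, and a cognition score below 23 multiplies
the odds by `exp(0.599) = 1.82`.

## The selection pipeline

Model development follows a five-step split-sample design:

1. **Cohort assembly** (`apply_eligibility`). Baseline-edentulous adults are
   excluded; so is any record missing the outcome or any analysis variable
   (complete-case analysis — no imputation). Each excluded record is
   attributed to exactly one reason, the first that applies in a fixed
   order (baseline status, outcome, then `cognition, loneliness, income,
   smoking, alcohol, dental_visit, self_rated_health, …`). The source
   analysis reported its per-variable deletion counts in essentially this
   order, with cognition by far the largest contributor; fixing the order
   makes the exclusion log comparable to such reports. The attribution rule
   for multiply-missing records is a convention, and a different convention
   would shift counts between reasons without changing the retained cohort.
2. **Selection/Test split** (`split_selection_test`). A one-time 70/30
   random partition; sizes round half away from zero, so a 4,288-record
   cohort splits 3,002 / 1,286. The Test set is untouched until step 5.
3. **Monte Carlo cross-validation** (`run_mccv`). The Selection set is
   repeatedly re-partitioned (500 replicates by default) into Training and
   Validate halves. `validate_size` is a count, not a fraction, and
   defaults to 1,286 — the Test-set size — giving Training sets of 1,716
   when n = 4,288. This reproduces the 3,002 = 1,716 + 1,286 arithmetic
   exactly (a 43% fraction of 3,002 would not give an integer) and makes
   validation AUCs directly comparable to the final Test AUC. All 32 models
   (`enumerate_models`: the six-variable core plus every subset of the five
   candidates) are fitted to the same Training partition within a
   replicate, so between-model AUC differences are paired. Partitions are
   simple random draws, unstratified; a draw leaving either half with a
   single outcome class is re-drawn (with a logged warning). Replicate `r`
   uses a child seed derived deterministically from `(seed, r)`.
4. **Selection** (`select_best`). The "best" model maximises the mean
   Validate AUC, but near-ties go to the smaller model. The
   `parsimony_tolerance` parameter (default 0.002) defines "near":
   among models within 0.002 of the maximum, the fewest-variable model
   wins. A strict 3-decimal tie rule alone cannot express a choice of a
   0.749 model over a 0.751 maximum, so the tolerance is exposed as a
   parameter; 0 gives the exact arg-max.
5. **Recalibration and validation** (`validate_final`, `bootstrap_auc`,
   `classification_metrics`). The selected model is refitted to the full
   Selection set, applied to the Test set, and its AUC bootstrapped with
   1,000 with-replacement samples of the full Test size; the 2.5th/97.5th
   percentiles give the 95% interval. Both the plain point AUC and the
   bootstrap mean are reported — the two are conflated in common usage, and
   they differ slightly. Classification metrics are computed at the
   prevalence cutpoint (the exact, unrounded observed event proportion of
   the evaluated data, by default), with `score >= cutpoint` counting as
   predicted positive. Single-class bootstrap resamples are re-drawn rather
   than dropped, preserving `B`.

## The synthetic cohort generator

`generate_cohort(synthetic_config())` draws cohorts whose defaults are the
published study conditions: n = 4,288; each categorical covariate drawn
from its published marginal frequency (e.g. 398/4,288 current smokers,
547/4,288 African American participants, 1,424/4,288 with cognition scores
below 23); age from Normal(66.3, 8.4) truncated to adults over 50 and
rounded to whole years (survey ages are integer-valued); and the outcome
Bernoulli with probability `exp(L)/(1+exp(L))` from the published
coefficients. Cognition is drawn as its Low/Normal dichotomy and then given
an integer 0–35 score from a discretised normal within the band — only the
dichotomy enters any model, so the within-band shape is inert.

Two aspects are deliberate design choices rather than published facts:

* **Dependence.** Only marginals are published; the joint covariate
  distribution of the real cohort is unknowable from the text. Covariates
  are therefore independent by default (`dependence = 0`). A single latent
  "disadvantage" factor is available (`dependence` in [0, 1)): it loads
  positively on education, income, smoking, dental visit, cognition,
  self-rated health and loneliness — the covariates that co-vary with the
  outcome in the published bivariate table — by shifting each variable's
  Gaussian cut-points, which preserves marginals while inducing positive
  association. Because the real correlation structure is absent under
  independence, the synthetic test AUC sits near 0.70 rather than the
  published 0.748; pipeline tests therefore assert behaviour (ordering,
  recovery, coverage), not the published AUC values.
* **Intercept re-solving.** With `target_incidence` set, the intercept is
  re-solved by monotone root-finding (`uniroot` on the expected incidence
  of the drawn covariates) so the cohort's expected incidence matches the
  target to within 1e-4; the published 12-year incidence is 9.7%.

Reproducibility: `generate_cohort` seeds a local RNG stream from
`config$seed` (restoring the caller's stream afterwards) and draws
variables in a fixed order, so a given `(n, seed)` is byte-identical across
calls. Changing `n` redraws the whole cohort; per-record counter streams
were considered and rejected because R's RNG API offers no cheap
counter-based substreams, and no use in the pipeline extends a cohort
in place.

## Numerical choices

* `fit_logistic` is a Newton/IRLS solver: convergence when the largest
  absolute coefficient step falls below 1e-8 or the log-likelihood change
  below 1e-10, at most 50 iterations; no regularisation (the reference
  coefficients are plain ML estimates). Complete or quasi-complete
  separation is detected as any coefficient diverging beyond ±15 and
  returned as a flagged, non-converged result rather than silent output.
  Within `run_mccv`, however, a quasi-separated training fit is still
  scored on the Validate set (with a logged count): its finite coefficients
  give valid ranked predictions — the affected category's risk is driven to
  0 or 1, which is the ML answer for a level with no observed events — and
  because the core factors are shared by all 32 models, excluding such fits
  would silently drop entire replicates (or entire runs, when a rare level
  such as "Other" race draws no events in a 3,002-record cohort) and bias
  the paired model comparison. Only fits that error or stall without
  separation are recorded as missing AUCs and excluded from the means.
* AUC is the Mann–Whitney concordance with half credit for ties, computed
  from mid-ranks; ties occur routinely in small or discretised synthetic
  data, and half credit keeps the statistic equal to the trapezoidal ROC
  area (`roc_curve` asserts this identity in tests).
* Factor-level "Type III" tests are likelihood-ratio tests (statistic
  `2Δℓ`, df = indicators dropped). Whether the reference analysis used
  Wald or LRT statistics is not determinable from its printed values; LRT
  was chosen as the better-calibrated default in moderate samples.
* Wald 95% intervals for odds ratios use z = 1.96; unadjusted 2×2 odds
  ratios use the Woolf log-scale interval with Haldane–Anscombe 0.5
  correction only when a zero cell is present.
* The age comparison in `table_one` defaults to Welch's unequal-variance
  t-test (`pooled_variance = TRUE` restores the pooled test); chi-square
  tests are Pearson without continuity correction, with an optional Yates
  switch for 2×2 tables. Tests on tables with a zero expected count are
  flagged invalid rather than computed.

## Problem sizes used in the checks

The package's property checks run at sizes chosen to make their
conclusions sharp but cheap: parameter recovery refits one 100,000-record
generated cohort (every coefficient recovered within ±0.1, about 2.5
standard errors at that n); selection consistency runs the full 32-model
MCCV at the study's selection size (n = 3,002, 100 replicates) 20 times;
bootstrap coverage checks 100 nominal-95% intervals (B = 1,000) on
1,286-record test sets against the generating equation's AUC estimated on
a 400,000-record cohort. Marginal and independence checks use
100,000-record cohorts (Cramér's V below 0.02 under independence).

## Limitations

* Synthetic cohorts emulate marginals and the outcome model, not the HRS's
  survey weights, household clustering, attrition, or the real joint
  covariate distribution; absolute discrimination on synthetic data is
  therefore not evidence about real-data discrimination.
* The pipeline is complete-case by design; it does not impute.
* No interactions are considered among the 32 candidate models, and no
  criteria beyond AUC (calibration, AIC/BIC) are used.
* The "Other" race category is treated as a substantive label; records
  with unknown race are excluded as missing.
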