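---
title: "Selecting digital biomarkers of physical frailty: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting digital biomarkers of physical frailty: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actifrail)
```

## The analysis this package implements

Under the Fried phenotype definition, an older adult is *pre-frail/frail*
(FG) when at least one of five criteria is present — slowness, weakness,
exhaustion, weight loss, inactivity — and *robust* (RG) otherwise. A
pendant sensor worn at the sternum for 48 h yields twelve daily-activity
features: walking cadence and four postural-transition features (slowness/
weakness indicators), longest walking bout and steps per walking episode
(exhaustion indicators), and total walking steps plus four posture
percentages (inactivity indicators). The pipeline asks which minimal subset
of those features identifies frailty status, via four stages:

1. **Descriptives.** Per-feature two-group comparison with normality
   screening, BMI-adjusted p-values, and Cohen's d effect sizes.
2. **Phenotype models.** Five fixed-feature-set binary logistic models
   (physical frailty, slowness, weakness, exhaustion, inactivity) with
   in-sample AUC.
3. **Balanced-bootstrap recursive feature elimination.** B pairs of
   balanced training / out-of-bag validation sets; per recursive loop with
   k active features, k logistic models per pair; one feature eliminated
   per loop by mean AUC; total fits exactly B·n(a+l)/2 with n = a − l + 1.
4. **Final model.** Out-of-bag validation of the selected subset, plus a
   fixed-coefficient four-feature scorer with the published raw-scale
   coefficients.

Because the original participant data are not deposited, every stage is
exercised against a synthetic cohort generator that reproduces the
published summary statistics. This vignette records the modelling
assumptions, the parameters that matter, and the design decisions taken
where the procedure was underdetermined.

## The synthetic cohort: what it emulates

`default_cohort_spec()` encodes the published cohort: 73 RG and 186 FG
participants; within-FG phenotype prevalences 0.694 (slowness), 0.640
(weakness), 0.301 (exhaustion), 0.091 (weight loss), 0.403 (inactivity);
and per-group mean/SD for each of the twelve features. Key design choices:

**Marginals.** Each feature is simulated from a truncated normal on its
support ([0, ∞) for counts and durations, [0, 100] for percentages) whose
underlying parameters are *numerically moment-matched* so the truncated
distribution has exactly the requested mean and SD. The two long-tailed
step-count features (longest walking bout, total walking steps) use a
log-normal matched in closed form instead: their printed SDs exceed or
approach their means (e.g. bout 1372.7 ± 1702.5 in RG), which a truncated
normal can only represent badly — the truncated-normal family cannot exceed
an SD/mean ratio of 1 on [0, ∞), and these features are strongly
right-skewed in real accelerometry.

**Dependence.** A Gaussian copula with an exchangeable latent correlation
(`within_group_correlation`, default 0.3) over the eight non-posture
features. Real activity features are correlated, and independent features
would make the multivariate models more accurate than the published ones;
0.3 keeps the correlation moderate and tunable.

**The posture composition.** The four posture percentages are a
composition of the 24-h day, and the published group means sum to exactly
100.0 in both groups. The posture block therefore gets its own latent
structure: four unit-length planar loadings whose SD-weighted sum is zero
(a closed polygon with side lengths equal to the four SDs), so the latent
posture sum is degenerate at zero and the percentage sum concentrates at
100. Each row's posture block is then renormalized to sum to exactly 100.
This keeps each percentage in [0, 100], the sum on the simplex, and the
per-feature means and SDs at their published values — three constraints
that a shared positive correlation factor cannot satisfy simultaneously.
A consequence worth knowing: the posture block is driven by two latent
factors, so posture features are mutually more constrained than in real
data.

**Phenotype flags.** FG rows draw the five flags as independent Bernoullis
and reject all-zero rows (the Fried rule forces at least one criterion).
Because rejection inflates marginal prevalences by roughly 4%, the
underlying rates are calibrated by fixed-point iteration so the
*conditional* within-FG prevalences equal the published ones. Weight loss
has no associated sensor feature and contributes only to frailty status.

**Phenotype coupling.** For the phenotype models to be learnable, FG
feature values must depend on which flags are set. Each feature class gets
a coupling intensity: binary for exhaustion and inactivity, and the mean of
the slowness and weakness flags (0, ½, 1) for the shared slowness/weakness
class. The FG marginal is split into per-intensity branches whose means are
shifted along the RG→FG direction by `coupling` × (RG−FG gap) ×
(intensity − mean intensity), with branch variances chosen so the FG
marginal mean *and* variance are preserved exactly. Sampling quantile-maps
the copula draw through the matched branch distribution, so supports are
respected without clipping bias. `coupling = 0` makes FG features
independent of the flags; the default `coupling = 1` separates flag-on and
flag-off rows by the full between-group gap.

Two structural facts follow from the published feature-phenotype map and
are deliberately not "fixed": slowness and weakness share all five of
their features, so those two models bound each other's discriminability
regardless of coupling strength (the published models show the same
pattern); and with robust rows included, phenotype models stay above
chance even at zero coupling, because robust participants are
phenotype-negative by definition and differ in every feature — the true
null case is an FG-only cohort, which is what the tests use.

**What the generator does not emulate.** Raw accelerometry and the
proprietary posture/gait algorithms; 24-h time series (only 48-h-averaged
features are produced); measurement error and day-to-day variability;
missing data; any association between demographics and the sensor
features (BMI differs by group but does not drive them, so
covariate-adjusted p-values on synthetic data behave like unadjusted
ones). A green test on synthetic data therefore establishes that the
*pipeline machinery* is correct at the published summary statistics — not
that the published cohort-specific results (a particular ranking, a
particular AUC) are reproduced.

## Descriptives

Cohen's d uses the unweighted pooled SD, `sqrt((s1^2 + s2^2)/2)`. The
sample-size-weighted variant gives 0.45 for walking cadence where the
published table prints 0.50; the unweighted variant reproduces eleven of
the twelve printed values to two decimals from the printed moments. The
twelfth (% of lying) computes 0.23 against a printed 0.24 under every
standard pooled-SD variant; the package reports the computed value and the
discrepancy is documented rather than absorbed.

Normality is screened per group with Shapiro–Wilk at α = 0.05; both groups
must pass for the pooled-variance t branch (equivalent to a two-group
one-way ANOVA), otherwise a rank-sum test is used — exact by full
enumeration of group assignments when the combined n ≤ 10 (correct under
ties), normal approximation with tie correction and no continuity
correction otherwise. The repeated-measures/GEE modelling of the original
analysis is not possible once features are 48-h averages; the BMI
adjustment is an ordinary least-squares fit `feature ~ group + bmi`, and
both adjusted and unadjusted p-values are reported.

## The logistic core

Fitting is iteratively reweighted least squares on z-scored features,
tolerance 1e-8 on the maximum coefficient change, 100 iterations.
Standardization is stored in the model, making prediction invariant to
affine rescaling of inputs; coefficients are reported back on the raw
scale. Balanced 73+73 bootstrap training sets can be linearly separable,
so the solver watches for divergence — a runaway standardized coefficient
(|β| > 15), a singular working system, or non-convergence with large
coefficients (|β| > 5, the signature of several redundant separating
features sharing the growth) — and refits with a small ridge penalty
(λ = 1e-3), flagging the model. This keeps a 130,000-fit loop running
unattended without human intervention.

AUC uses the rank formulation with ties counted ½, identical to
trapezoidal integration of the ROC curve. Classification metrics use a
0.5 probability threshold by default (no operating point is published);
metrics with zero denominators are reported as missing rather than zero.
Probabilities are oriented as P(pre-frail/frail); the published
four-feature model's negative coefficients on robust-enriched features
confirm that orientation. That scorer applies its printed coefficients to
*raw* inputs — the magnitudes (e.g. −0.0341 per step of longest bout) only
make sense unstandardized — and its tiny β₃ on cadence is used exactly as
printed.

## The elimination loop

Per pair, the larger class is subsampled without replacement to the
smaller class's size, the balanced pool is resampled with replacement
*within class* (so training sets are exactly 50/50 — resampling the pool
as a whole would only balance in expectation), and the out-of-bag pool
rows form the validation set; single-class validation sets trigger a
redraw with a budget of 100 attempts.

The published elimination step admits two readings of "k models with k
features": k leave-one-feature-out models, or k univariate models. Both
are implemented behind `criterion`; `leave_one_out` is the default because
successive loops remain informative (univariate rankings barely change
between loops) and it matches standard backward elimination — under it,
"remove the feature with the lowest AUC" inverts to removing the feature
whose *omission* model has the highest mean AUC. Ties eliminate the
feature latest in the input ordering, deterministically. Mean AUCs per
candidate are averaged over pairs on the training sets (the published
figure's convention); the final validation table uses the out-of-bag sets.
Confidence intervals are normal-approximation CIs of the *mean* across
pairs (mean ± 1.96·SD/√B): the published intervals (e.g. 79.4–79.7 around
79.5 at B = 2000) are far too narrow to be percentile intervals of the
pair-level distribution.

Subset selection takes the smallest k whose mean training AUC falls in the
acceptable band (default 0.7–0.8) and whose top-k features cover every
phenotype class present in the ranking, falling back (with a warning) to
the AUC-only solution, then to the best-AUC size. On synthetic cohorts the
band/coverage combination frequently has no joint solution — the synthetic
multivariate AUC rises through the band before all three classes appear —
which the fallback handles; the published four-feature selection emerges
from the published ranking, not from any synthetic draw.

## Numerical choices

- Truncated-normal moment matching: Nelder–Mead on (μ, log σ) against the
  closed-form truncated moments, relative tolerance 1e-14, cached per
  parameter set; targets with an infeasible SD/mean ratio (possible under
  strong coupling) match as closely as the family allows and warn.
- Flag-rate calibration: fixed-point iteration to 1e-12.
- The moment-fidelity test uses estimator-appropriate standard errors: the
  SD of a log-normal sample has a kurtosis-aware SE,
  `sd·sqrt((κ−1)/(4n))`, an order of magnitude wider than the
  normal-theory `sd/√(2n)` for these features.
- Demographics: age, height, and BMI are drawn per group from the
  published moments; weight is derived as BMI·height² because the
  published weight/height/BMI triplets are mutually inconsistent and BMI
  is the only demographic the analysis adjusts for.
- Every random stage takes an explicit seed and restores the caller's RNG
  state; identical spec + seed reproduces cohorts, pairs, rankings, and
  reports byte-for-byte.

## Known limitations

- Synthetic cohorts are more separable than the real one (the published
  11-feature training AUC is 79.5%; synthetic cohorts at the default
  correlation run higher), so absolute synthetic AUCs are not comparable
  to the published ones — fit counts, orderings, invariants, and
  formula-level results are.
- The published feature ranking is internally inconsistent as printed (one
  feature appears at two ranks); the package reproduces ranking
  *mechanics*, not that table.
- Slowness and weakness models cannot exceed the discriminability their
  shared feature set allows, in the package as in the published analysis.
- No multiclass staging (pre-frail vs frail), no alternative learners, no
  regularization paths, and no raw-signal processing.
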