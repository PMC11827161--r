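---
title: "Modelling life-course cardiometabolic trajectories by pregnancy history"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling life-course cardiometabolic trajectories by pregnancy history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Women who experience adverse pregnancy outcomes (APOs) — gestational
hypertension, preeclampsia (PE), gestational diabetes (GD), preterm birth
(PTB, spontaneous or medically indicated), small- or large-for-gestational-age
births (SGA/LGA), recurrent miscarriage, stillbirth — carry an excess risk of
cardiovascular disease in later life. A central question is whether pregnancy
*causes* that excess or *unmasks* a pre-existing adverse cardiometabolic
profile. Answering it requires comparing the full life-course trajectory of
routinely measured risk factors (blood pressure, BMI, cholesterol, glucose)
between women with and without each APO, from years before the first
pregnancy to more than a decade after.

`apotraj` implements that comparison as a reusable pipeline for
electronic-health-record (EHR) style data: a women table (baseline
covariates), a pregnancy register (one row per pregnancy with per-pregnancy
APO flags), and a long table of repeated measurements at irregular times.
Because the motivating data source is licence-restricted, the package also
ships a calibrated synthetic cohort generator with known ground-truth
trajectories, so every stage of the pipeline is validated by parameter
recovery rather than by unverifiable output.

# The model

For measurement $j$ of woman $i$, the package fits the two-level linear
model

$$ y_{ij} = x_{ij}'\beta + u_i + e_{ij}, \qquad
   u_i \sim N(0, \sigma_u^2), \quad e_{ij} \sim N(0, \sigma_e^2), $$

a random-intercept multilevel model: the woman-level intercept $u_i$ induces
compound-symmetry correlation among a woman's repeated measures. A
sensitivity variant adds a random slope on the time basis with an
unstructured $2 \times 2$ random-effect covariance.

Non-linearity in time is handled with **fractional polynomials** (FPs):
powers from $S = \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$, where power 0 denotes
$\log x$ and a repeated power $p$ contributes $x^p$ and $x^p \log x$. Because
FP arguments must be positive while the time axis runs from 10 years before
to 15 years after the first pregnancy, time is first mapped through an affine
positivity transform $x = (t - \mathrm{shift})/\mathrm{scale}$ fixed from the
analysis *window* (default $[-10, 15]$: shift $-11$, scale $10.4$, placing
$x$ in $(0, 2.5]$). Fixing the constants from the window rather than the
observed times makes the basis identical for fitting and prediction and
across runs.

On the time axis the fixed-effect design is the full factorial expansion

$$ \text{intercept} + f_k(t) + A + P + f_k(t)\!\cdot\!A + f_k(t)\!\cdot\!P
   + A\!\cdot\!P + f_k(t)\!\cdot\!A\!\cdot\!P + \text{covariates}, $$

where $A$ are exposure-group indicators and $P$ indicates a measurement
after the first pregnancy start (strictly $t > 0$; a measurement exactly at
$t = 0$ is pre-pregnancy). The three-way terms let each group have its own
curve shape before and after pregnancy. On the age axis the $P$ terms are
omitted: the before/after split is a property of time relative to pregnancy,
not of age, and the literal design described for the time axis is the only
place the three-way construction is stated. Covariates are age at first
pregnancy, Townsend deprivation quintile indicators, ethnicity indicators,
smoking, parity (truncated at 5), non-singleton pregnancy, and three
medication flags; fasting status is added for glucose only. Categorical
covariates enter as indicator sets with the most frequent level as
reference.

## Estimation

Estimation is by full **maximum likelihood**, not REML, because FP selection
and interaction assessment compare models that differ in their fixed
effects; REML deviances would not be comparable. Profiling over the variance
ratio $\lambda = \sigma_u^2/\sigma_e^2$ gives closed-form generalised least
squares at each $\lambda$, and the compound-symmetry structure reduces every
likelihood evaluation to per-woman sufficient statistics (column sums),
so one evaluation costs $O(p^2)$ after a single data pass. The profiled
deviance is minimised on a 49-point log grid over $\lambda \in [10^{-8},
10^4]$ with golden-section refinement (tolerance $\sim 10^{-10}$ in
$\log\lambda$); the $\lambda = 0$ boundary is always compared explicitly, so
data without between-woman variance fall back to ordinary least squares.
The implementation is checked in the test suite against a brute-force dense
covariance likelihood maximiser and against `lme4` at $10^{-6}$ tolerance.
Women with a single measurement are retained; they inform the fixed effects
and the residual variance.

The random-slope variant parameterises the random-effect covariance through
its Cholesky factor (so it stays positive semi-definite, and the zero-slope
boundary is admissible) and starts the optimiser at the intercept-only
optimum, which guarantees the nested-deviance inequality.

## FP selection

Powers are selected on a *baseline* model — FP terms and their products
with the post indicator (time axis), exposure main effects, the post
indicator, and covariates, with a random intercept — and then frozen before
the group interactions are added, so that power selection cannot leak into
group contrasts. One FP specification serves an outcome/axis combination.
The FP-by-period products matter: without them every candidate is scored on
a single compromise shape that the final (period-split) model never fits,
near-equivalent bases become interchangeable, and the selected powers
wobble from seed to seed — including towards bases such as $x^{-2}$ whose
edge behaviour degrades predictions at the window boundary.

Within each degree the candidate with the smallest deviance wins (8
candidates of degree 1; 36 of degree 2). Between degrees the package applies
the conventional closed test from the FP literature: the best degree-2 model
replaces the best degree-1 model only when its deviance improvement exceeds
$\chi^2_{2,0.95} \approx 5.99$. A raw minimum-deviance rule across all 44
candidates would select degree 2 almost surely (nested ML deviances strictly
decrease), making degree-1 truths unrecoverable; the closed test restores
selection consistency, which the test suite verifies by recovering powers
$(-0.5)$ from data generated with that shape. Exact ties resolve to the
lower degree, then enumeration order.

## Prediction

Trajectories are population-average predictions at the mean covariate vector
of the fitting rows ("average levels of the included covariates"): for group
$g$ and grid point $t$, the term vector combines the FP basis, group
indicators, the post indicator, and the stored covariate means; the estimate
is $x'\hat\beta$ with Wald 95% limits $x'\hat\beta \pm 1.96\sqrt{x' \hat V
x}$. Group differences (`contrast()`) use the same machinery; identical
covariate means cancel exactly.

# Exposure derivation

All exposures are *any-pregnancy* definitions over a woman's full pregnancy
history. The APO count sums per-pregnancy contributions of gestational
hypertension, PE, GD, PTB (either type), SGA, LGA and stillbirth — a
pregnancy with both PE and SGA contributes two — plus one if the woman had
three or more miscarriages (not necessarily consecutive); categories are 0,
1, 2, 3+. One or two miscarriages and congenital anomalies contribute
nothing. A `distinct_type` switch counts each APO type at most once per
woman instead (the default counts every occurrence).

Comparator rules: in the SGA analysis, women with LGA are excluded from the
comparator group and vice versa; PTB is a three-group contrast (none /
spontaneous / indicated; the rare woman with both types across pregnancies
is classed indicated); the any-APO contrast excludes women who are
unclassifiable (no live birth, or congenital-anomaly history only). Women
whose birth-derived flags are missing (no hospital linkage) are excluded
from the corresponding single-APO contrasts, and their missing flags
contribute zero to the count.

Analysis filters: measurements during pregnancy are dropped (recomputed from
the pregnancy intervals, never trusted from an input flag), as are
measurements outside the analysis window — the default $[-10, 15]$ years
matches the presented trajectory range and keeps extrapolation out of FP
choice. Rows missing the deprivation quintile (about 0.1%) are dropped.
Eligibility is `"any"` (at least one retained measurement) or
`"pre_and_post"` (at least one on each side of the first pregnancy).

# The synthetic cohort generator

The generator emulates the *printed, joint* structure of a UK primary-care
pregnancy cohort; its defaults are the packaged calibration and are not
meant to be tuned per analysis.

**Covariates.** Age at first pregnancy is a truncated normal on [14, 45]
whose underlying parameters are solved so the truncated mean and SD equal
27.1 and 6.6 years; deprivation quintiles, ethnicity (White / non-White /
unknown), smoking (45%), parity (41.6/28.1/15.0/8.0/7.2% for 1–5),
multiple-pregnancy history and medication flags follow the configured
marginals. A woman-level linkage indicator (54.5%) controls whether
birth-derived flags (PTB, SGA, LGA) are derivable; for unlinked women they
are missing, which reproduces the arithmetic of a cohort where those
prevalences are reported on a hospital-linked subset while the APO count is
reported on everyone.

**APO structure.** Each woman draws a latent risk class (protected /
average / high-risk) that shifts all per-pregnancy APO logits by a loading;
gestational hypertension and diabetes recur across pregnancies (the first
repeat is boosted, further repeats suppressed); PE and GD raise the
same-pregnancy odds of their clinical sequels (SGA/indicated PTB, and LGA)
with the no-trigger arm rescaled so marginals are unchanged; first
occurrences are dampened once a woman has accumulated two counted APOs
(saturation); and miscarriage follows a recurrent-loss chain with its own
boost. Mutually exclusive pairs (PE/gestational hypertension, SGA/LGA,
spontaneous/indicated PTB) are drawn with marginal-preserving conditional
probabilities. Per-pregnancy intercepts are solved exactly by
one-dimensional root finding against the woman-level prevalence targets,
integrating over the risk classes, the parity distribution and the
miscarriage-history chain (a small dynamic program). The handful of shape
parameters (class probabilities, loading, recurrence, comorbidity,
saturation) were calibrated once against the published APO-count
distribution (71.7/21.2/5.7/1.5%) and then frozen; the woman-level
prevalence targets themselves are matched by construction.

**Ground-truth curves.** Each APO-count group's true mean for each outcome
is a single fractional polynomial with powers $(0, 1)$ on the transformed
time axis, interpolating three anchor values (at $-10$, $0$ and $+10$ years)
exactly and extending smoothly to $+15$. The systolic-BP anchors at $\pm 10$
years are the published predicted values (112.9/115.1/116.8/119.6 mmHg
before; 119.5/121.2/124.3/127.1 mmHg after, for 0/1/2/3+ APOs); the $t = 0$
values and all non-BP outcome anchors are package choices at clinically
plausible levels. Keeping the truth inside the FP family the estimator
searches is deliberate: recovery error then measures *estimation* error, not
basis mismatch, and the noise-free limit reproduces the truth to numerical
precision (verified in the tests at $3\times 10^{-9}$ mmHg). A truth with a
kink at $t = 0$ was tried and rejected: power selection on the baseline
model (which has no FP-by-period terms) then settles on compromise powers
and leaves a few tenths of a mmHg of irreducible basis bias.

**Measurements.** Values are the group truth curve plus *centred* covariate
effects (so group curves stay marginal over covariates), a woman-level
random intercept (SD 9 mmHg for systolic BP) and residual noise (SD 8 mmHg),
with implausible draws rejected and redrawn (e.g. systolic BP outside
60–250 mmHg). Per-woman measurement counts are gamma-mixed Poisson (negative
binomial) with APO-group rate multipliers — the informative-observation
mechanism — calibrated so that BP has a conditional-on-observed median of 6
measurements per woman (IQR 3–11) and 91% coverage among women with only
healthy pregnancies; cholesterol and glucose match their printed coverage
(21%, 44%) and median (1) directly. For BMI a single negative-binomial
family cannot reach 87% coverage and a median of 3 simultaneously; the
median was prioritised. Measurement times are uniform on the window
(homogeneous base process); measurements falling inside a pregnancy interval
are generated and flagged, and excluding them is the analyst's job, mirroring
real pipelines. Outcomes are generated independently within woman given the
group and covariates; within-woman cross-outcome correlation beyond that is
not emulated.

**What passing recovery tests does and does not show.** The generator
reproduces printed marginals, the APO-count joint feature, availability
differences and anchor-valued trajectories. It does not emulate coded-event
streams, visit clustering, measurement error that depends on unobserved
health state, or outcome-dependent observation *within* group — so passing
parameter recovery here demonstrates correctness of the estimation
machinery under the stated data-generating process, not robustness to every
informative-observation mechanism a real EHR can produce.

# Numerical choices and degenerate inputs

* Deviance convergence: grid + golden-section refinement, with an explicit
  $\lambda = 0$ comparison; boundary fits are flagged, not hidden.
* Noise-free data ($\hat\sigma_e^2 \to 0$) are handled by flooring the
  profiled variance at $10^{-280}$, keeping deviances finite and orderable.
* Rank deficiency is an error naming the offending columns, not a silent
  drop; an all-zero exposure column (a masked-out group) is an error.
* FP arguments that leave the positivity region raise an error; they are
  never clipped.
* Measurements exactly at $t = 0$ are pre-pregnancy (the post indicator is
  strict), and pregnancies are closed intervals for the in-pregnancy filter.
* Simulation problem sizes in the packaged checks — 20,000 women for anchor
  recovery (with 20 replicates for the bias check), 100,000 for marginal
  calibration, 50,000 for the observation-process median, 2,000 × 50
  replicates for selection consistency — were chosen to keep Monte-Carlo
  error well below the corresponding decision bands.

# Known limitations

* The generator's pregnancy spacing (uniform 1–4 year gaps, fixed
  gestation lengths) is plumbing, not demography.
* The latent risk class is a calibration construct; its three-class form
  reproduces the printed APO-count distribution but is not an estimate of
  any real frailty distribution.
* The age-axis model omits pre/post terms by design (see above); if the
  original analysis included them, age-axis contrasts may differ in shape
  near first pregnancy.
* Wald intervals with the normal critical value are appropriate at EHR
  sample sizes but anti-conservative for very small cohorts.
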