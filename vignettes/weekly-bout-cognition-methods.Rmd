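---
title: "Methods: weekly varying-coefficient models for activity bout distributions and day-level cognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weekly varying-coefficient models for activity bout distributions and day-level cognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(boutcog)
```

This vignette is the package's own account of the statistics it implements:
the model and its assumptions, what the synthetic-data generator does and
does not emulate, the tunable parameters with their defaults and rationale,
the numerical choices, and the known limitations. Every empirical statement
here is one the test suite or `scripts/acceptance.R` computes; nothing is
quoted from external data.

## 1. The analysis in one paragraph

Two weeks of thigh-accelerometer wear give, per subject-day, a stream of
posture/MET events. These are segmented into sedentary (SED), light (LPA)
and moderate-to-vigorous (MVPA) activity bouts with a one-minute recordable
floor. For each subject and day of week $d \in \{1,\dots,7\}$ (1 = Sunday),
the bout-length sample of each class is summarized by a power-law tail
index $\alpha$ and an inequality index $G$ (Gini). Day-level cognition —
median response time over accurate symbol-search trials, and mean correct
trials — is regressed on these indices with coefficients that are smooth
functions of the day of week, a subject random intercept absorbing
within-person correlation, and demographic adjustment. Six models are fit:
2 outcomes $\times$ 3 bout classes.

## 2. The indices

For a bout-length sample $x_1,\dots,x_n \ge x_m$ (with $x_m$ = 1 min, the
instrument floor — a configuration constant, never the per-sample minimum):

* **Alpha**: $\alpha = 1 + 1/M$, $M = \tfrac1n \sum_i \log(x_i/x_m)$.
  If lengths follow a power law with density $\propto x^{-\alpha}$ above
  $x_m$, this is the maximum-likelihood estimate of $\alpha$; the
  acceptance suite verifies consistency to within 0.05 on samples of
  $10^4$. When every bout sits at the floor, $M = 0$ and the index is
  degenerate; it is returned as missing (not $+\infty$) so design matrices
  stay finite, and the affected rows are dropped per model with a count.
* **Gini**: $G = \sum_i\sum_j |x_i - x_j| / (2 n \sum_i x_i)$, in
  $[0, 1 - 1/n]$. The implementation uses the algebraically identical
  sorted form ($O(n\log n)$); the test suite holds it against the literal
  double loop at $10^{-10}$ on a thousand random samples, and the
  generator's truth tables use the double-loop form precisely so the two
  code paths stay independent.

**Day-of-week aggregation.** A 14-day protocol visits each day of week
twice. The default (`dow_aggregation = "pool"`) pools the bout lengths of
the (up to) two valid same-weekday dates and indexes the pooled sample;
`"per_day_mean"` indexes each date and averages. Both are exposed because
they answer slightly different questions: pooling estimates the weekday's
underlying length distribution from all available bouts, while the
per-day mean matches a strictly day-level generative model. Under heavy
tails the two differ systematically — with the generator's defaults the
pooled-sample Gini regressor recovers only about 75–80 % of an effect
planted on daily indices (an estimand shift, not an estimator bias; the
recovery experiments in the acceptance suite therefore run in
`per_day_mean` mode, where the regressor and the generative quantity
coincide and recovery is unbiased).

## 3. The varying-coefficient model

For subject $i$ and day of week $d$:

$$Y_i(d) = \beta_0(d) + \alpha_i(d)\beta_1(d) + G_i(d)\beta_2(d) +
N_i(d)\beta_3(d) + \mathrm{Age}_i\beta_4(d) + \mathrm{Sex}_i\beta_5(d) +
\mathrm{Edu}_i\beta_6(d) + b_i + \varepsilon_i(d)$$

with $b_i \sim N(0,\sigma_b^2)$, $\varepsilon_i(d) \sim N(0,\sigma^2)$,
and education entering as two indicators against an "up to high school"
reference, so eight coefficient curves in total.

The functional domain has only seven grid points, and it is a *circle*:
Saturday and Sunday are neighbours. Each curve is therefore expanded in
$K$ wrapped cubic B-splines on a circle of circumference 7
(`cyclic_basis()`), a partition of unity whose null space under the
circulant difference penalty (`cyclic_penalty()`, order 2) is exactly the
constant curve — so a curve's *level* is never shrunk, only its
within-week variation. Defaults: $K = 5$ (flexibility vs. identifiability
on 7 points); $K = 7$ with zero penalty is the saturated escape hatch,
which the tests prove equal to seven separate day-stratified OLS fits to
$10^{-6}$ and, with the random intercept, equal to `lme4::lmer` on the
fully interacted fixed-effects model.

**Estimation.** The penalized fit is cast in the standard
smoothing-as-mixed-model form: coefficients have prior precision
$\lambda_j S/\phi$ per curve plus $\lambda_b I/\phi$ on the subject block,
and the restricted likelihood (with $\phi$ profiled out) is minimized over
$\log_{10}\lambda$ by deterministic coordinate descent — a coarse grid
bracket per coordinate, then golden-section refinement to a $10^{-8}$
score tolerance, with stalled coordinates skipped after two sweeps. The
subject block is eliminated analytically (block inversion using the
per-subject counts), so each evaluation costs one $8K \times 8K$ Cholesky
regardless of cohort size. A minimal ridge ($10^{-10}$ of the diagonal) is
the fallback if the saturated unpenalized system is numerically singular.

**Uncertainty and testing.** Pointwise intervals use the Bayesian
coefficient covariance $\phi(C^\top C + S_\lambda)^{-1}$, which accounts
for the penalty. The per-curve test is a Wald-type statistic on the curve
values with a rank-aware pseudo-inverse truncated at the curve's
(alternative) effective degrees of freedom — the standard remedy for the
over-conservatism of a full-rank Wald test under shrinkage: a true null
curve is smoothed to its unpenalized constant, and testing that constant
against $\chi^2_1$-type reference keeps the size near nominal. The
acceptance suite measures the rejection rate of the Gini curve test over
500 null cohorts of 200 subjects and requires it in $[0.03, 0.07]$ at the
5 % level. `wald_test()` with `rank = NULL` retains the plain
numerical-rank pseudo-inverse for unpenalized use.

**Adjusted $R^2$** is $1 - [\mathrm{RSS}/(n-\mathrm{edf})]/
[\mathrm{TSS}/(n-1)]$ with edf the trace of the full smoother (subject
block included); it is stated explicitly because penalized-model $R^2$
conventions vary, and it is not comparable across packages that exclude
the random-intercept block from the fitted values.

**Scaling.** Predictors enter on their natural scales by default.
`z_scale = TRUE` standardizes the continuous predictors and reports
per-SD curves (identical fits, rescaled coefficients); neither mode is
claimed to match any externally reported effect-size scale, which is why
`mean_abs_effect()` — the mean of $|\hat\beta_j(d)|$ over the week — is
reported alongside whichever scale is chosen. Prediction invariance to
affine recoding of binary covariates is exact in the saturated
unpenalized parameterization and only approximate under penalization
(recoding moves covariate level into the intercept curve, whose roughness
is penalized separately); the suite tests the exact case.

## 4. The synthetic cohort generator

`generate_cohort()` emulates the full observation process; defaults are
the study conditions the package targets and are fixed, not tuned:

| Parameter | Default | Why |
|---|---|---|
| `n_subjects`, `n_days` | 87, 14 | target design size; 14 days = each weekday twice (start date is a Sunday) |
| `prompts_per_day`, `trials_per_session` | 4, 18 | EMA protocol: 4 semi-random prompts ≈ 2.5 h apart in a 06:00–22:00 wake window, 18 trials each |
| `bout_count_means` | 28.4 / 34.7 / 6.9 | typical daily SED/LPA/MVPA bout counts for community-dwelling older adults |
| `bout_length_tail` | 2.5 / 3.0 / 3.5 | power-law density exponents (= population alpha): sedentary bouts heaviest-tailed; implied population Gini ≈ 0.50/0.33/0.25 |
| `tail_sd` | 0.3 | subject-level heterogeneity of the tail exponent, calibrated so the day-level Gini ICC is ≈ 0.5 — the single-day reliability scale reported for accelerometer fragmentation metrics; without it the indices would be nearly pure noise day to day |
| `subject_sd`, `residual_sd` | RT 500/330 ms; accuracy 0.33/0.35 | day-level outcome ICCs ≈ 0.70 (RT) and ≈ 0.47 (accuracy), the plausible EMA range, with total SDs on the scale of observed cohort descriptives |
| `compliance` | 0.75 | gives ≈ 5 % of valid days with a single completed session and < 1 % of days with no session |
| `low_wear_rate` | 0.035 | together with missed prompts, ≈ 4 % of person-days fail the validity rules |
| `rt_sigma_log` | 0.35 | within-session trial RT spread; log-normal, so the session median equals the day mean |

Bout lengths are Pareto with scale fixed at the 1-minute floor, so the
alpha index has a known population analogue (`bout_length_tail` itself) —
that is what makes estimator-consistency and recovery testable. Lengths
are capped at 600 min for realism; at the default exponents the cap is
essentially never binding for the index values. Each day's bouts are laid
down in random order, separated by `OTHER` (quiet standing) filler so that
events exactly tile the wake window; each bout is split into 1–3
contiguous events with MET values drawn inside the class's defining
interval, which exercises the extraction merge logic. Day-level outcomes
are linear in the *realized* per-day indices with the planted
day-of-week coefficient curves, plus subject intercept and residual;
trials are then generated around the day means. RNG streams are derived
per subject and per day from the master seed, so identical config + seed
reproduce the tables byte for byte.

`cohort_table()` is the vectorized day-level path used by the Monte-Carlo
studies (thousands of cohorts): identical statistical structure at day
grain, no event/trial plumbing, all days valid. The event-level path is
separately validated (generator truth vs. pipeline indices agree to
$10^{-12}$; planted low-wear days are recovered exactly by the QC stage).

`weekday_effect_curve()` builds the planted "quiet Sunday" pattern — an
exact zero on Sunday (hard constraint) with weekdays held near a constant
by least squares — inside the $K = 5$ basis span, so pattern-recovery
experiments test estimation rather than basis approximation.

**What the generator does not emulate:** circadian structure within the
day (bout order is exchangeable); serial correlation between consecutive
days beyond the stable subject effects; practice/fatigue trends in the
cognitive task; posture misclassification and non-wear other than the
injected low-wear days; weekday/weekend differences in bout *counts*
(only planted effect curves make weekdays special). Passing tests on
synthetic data therefore certify the pipeline's statistical machinery,
not the field validity of any particular real-world finding.

## 5. Quality control and alignment

A protocol day is valid iff wear time within the wake window is ≥ 10 h
and at least one session is complete (all 18 trials); when both rules
fail, the recorded reason is `low_wear`. Outcomes for a (subject, dow)
cell average the valid dates; a day whose only complete sessions had zero
accurate trials stays valid for the accuracy outcome and contributes a
missing RT. Bouts spanning midnight belong to their start date and are
not split; events are contiguous iff the gap is ≤ 1 s (event files are
nominally gapless; the tolerance absorbs rounding, and timestamps
round-trip through millisecond text). Study day and study week are never
covariates.

## 6. The power study

`simulate_power()` reproduces the conventional Monte-Carlo power analysis
for the multilevel design: $y_{ij} = b_i + \beta x_{ij} + e_{ij}$ with
unit total variance split by the ICC, a standard-normal day-level
covariate, and the random-intercept model (`lme4::lmer`, REML) as the
fitted test, rejecting on the Wald p-value of $\hat\beta$. Because the
covariate varies within subject, the effective residual is the
within-subject variance $1-\mathrm{ICC}$: power *increases* with ICC at
fixed $\beta$ (the suite tests this direction). The observed ICCs of the
real outcomes are not public, so results are reported over an ICC grid —
defaults 0.45 and 0.70, the plausible accuracy-like and RT-like values —
rather than as a single number; at $n = 87 \times 14$ the acceptance run
shows the standardized grid $\beta \in \{0.05, 0.07, 0.10\}$ spans power
from ≈ 0.65 (low ICC, small effect) to ≈ 1.0, with the $\beta = 0.10$
cell at or above 0.99 for every grid ICC. Boundary (singular) fits —
expected in ~half of replicates when the true ICC is ≈ 0 — are counted
and reported but kept in the denominator, since the fixed-effect Wald
test remains well defined at the variance boundary.

## 7. Problem sizes and determinism

The shipped test suite simulates at the scales its questions need:
calibration uses 500 cohorts of 200 subjects; pattern recovery 200 cohorts
of 200 subjects; constant-effect recovery 16 cohorts of 300 subjects;
power cells 500 simulations each; the saturated-fit oracles run at 60–300
subjects. `scripts/acceptance.R` uses 200 calibration cohorts at the
87-subject design size and 400 simulations per power cell. All randomness
flows from explicit seeds; REML optimization is deterministic (no random
starts), and reruns with the same seed produce identical manifests.

## 8. Known limitations

* The subject random intercept is scalar; a functional (per-curve) random
  effect would capture subject-specific weekly shapes but is not
  identifiable at 7 grid points with two replicates per point.
* Accuracy is modeled as a Gaussian day-level mean. With 18-trial sessions
  near ceiling this is serviceable but ignores the bounded support.
* The Wald curve test's effective-df truncation is approximate; its size
  is verified by simulation at the package's design sizes, not proven.
* Pooled versus per-day-mean aggregation changes the estimand under heavy
  tails (Section 2); analyses should state which mode they used.
* No multiple-testing correction across the six models is applied, by
  design; downstream users comparing many curves should correct as their
  context requires.
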