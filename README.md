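# boutcog

**Day-of-week varying-coefficient analysis of activity bout distributions
and ambulatory cognition.**

## The problem

How physical activity and sedentary time are *accumulated* — many short
fragments versus a few sustained stretches — may matter for late-life
cognitive health beyond total volume. In daily-diary studies, older adults
wear a thigh accelerometer for two weeks while answering brief smartphone
cognitive tests (a speeded symbol-search task) several times a day. This
package provides the full analysis pipeline for such designs:

1. **Bout segmentation.** Accelerometer event streams (posture + MET value
   per event) are merged into maximal contiguous bouts of sedentary
   behaviour (< 1.25 METs, seated/reclined), light activity (LPA,
   1.25–2.99 METs) and moderate-to-vigorous activity (MVPA, ≥ 3 METs),
   with a 1-minute recordable floor.
2. **Distribution indices.** For each subject, day of week *d* (1 = Sunday
   … 7 = Saturday) and bout class, the bout-length sample
   {*x*₁, …, *x*ₙ} is summarized by
   - the **alpha index**, α = 1 + 1/M with M = (1/n) Σᵢ log(*x*ᵢ/*x*ₘ),
     where *x*ₘ is the 1-minute floor — a power-law-tail summary (higher α:
     short bouts dominate, long bouts are rare); it is the maximum-likelihood
     exponent estimate when bout lengths are Pareto above the floor;
   - the **Gini index**, G = ΣᵢΣⱼ |*x*ᵢ − *x*ⱼ| / (2 n Σᵢ *x*ᵢ) ∈ [0, 1) —
     half the relative mean absolute difference (0 = perfectly even bout
     lengths, → 1 = highly unequal).
3. **EMA cognition.** Symbol-search trials are aggregated per session
   (18 trials = complete) and per day: median response time (RT) over
   accurate trials, and the mean number of correct trials.
4. **Quality control.** A protocol day is valid with ≥ 10 h of wear during
   waking time and ≥ 1 complete session; analysis rows are day-of-week
   matched observations (Yᵢ(d), αᵢ(d), Gᵢ(d), Nᵢ(d)).
5. **The model.** A day-of-week varying-coefficient regression

   Yᵢ(d) = β₀(d) + αᵢ(d)β₁(d) + Gᵢ(d)β₂(d) + Nᵢ(d)β₃(d)
           + Ageᵢβ₄(d) + Sexᵢβ₅(d) + Eduᵢβ₆(d) + bᵢ + εᵢ(d),

   where every βⱼ(d) is a smooth function on the *weekly circle* (cyclic
   B-spline basis with a circulant difference penalty, so Saturday and
   Sunday are smoothly tied), bᵢ is a subject random intercept, and
   smoothing parameters and variance components are estimated by REML.
   Pointwise intervals use the Bayesian coefficient covariance; each whole
   curve gets an approximate Wald-type test on its effective degrees of
   freedom. Two outcomes × three bout classes = six models per study.
6. **Synthetic cohorts and power.** A generator emulates the full design
   (event streams, EMA prompts, demographics) with *planted* day-of-week
   effect curves and known truth tables, and a Monte-Carlo power study
   covers the multilevel (days-in-subjects) design over a grid of effect
   sizes and intraclass correlations.

## Worked example

Simulate a 120-subject cohort in which higher MVPA bout-length inequality
(Gini) speeds RT on weekdays but not Sunday, then run the pipeline:

```r
library(boutcog)

curve <- weekday_effect_curve(-900)       # 0 on Sunday, ~ -900 ms/unit on weekdays
cfg <- sim_config(n_subjects = 120,
                  planted_beta_gini = list(rt = list(MVPA = curve)))
cohort  <- generate_cohort(cfg, seed = 42)
ex      <- summarize_days(cohort$events)
cogdays <- cognitive_days(cohort$trials)
valid   <- flag_valid_days(ex$day_summary, cogdays)
ix      <- dow_indices(ex$bouts, valid[valid$valid, c("subject_id", "date")],
                       aggregation = "per_day_mean")
tab     <- build_analysis_table(valid, cogdays, ix, cohort$demographics)
fit     <- fit_model(tab, model_spec("median_rt", "MVPA"))
fit
```

```
Day-of-week varying-coefficient fit: median_rt ~ MVPA indices
  n = 840 rows, 120 subjects (0 dropped); K = 5, smoothing = REML
  sigma^2 = 6.751e+04; subject intercept var = 3.13e+05; adj. R^2 = 0.819
  Wald-type curve tests:
         term   stat   df        p
    intercept  24.61 1.00 7.03e-07
   alpha_MVPA   4.30 1.00    0.038
    gini_MVPA 103.04 4.94  < 2e-16
  nbouts_MVPA   2.20 1.01    0.140
          age   0.22 1.00    0.638
          sex   0.30 1.00    0.584
  edu_college   0.00 1.00    0.947
 edu_advanced   0.05 1.00    0.830
```

The Gini curve is clearly nonzero (Wald p < 2e-16 on ≈ 5 effective df),
while the bout-count and demographic curves are flat nulls. The fitted
curve tracks the planted weekday pattern:

```r
subset(fit$curves, term == "gini_MVPA")[, c("d", "estimate", "lo", "hi")]
```

```
  d estimate      lo      hi
1 1   -378.1  -680.4   -75.8
2 2   -851.9 -1146.5  -557.2
3 3  -1338.7 -1639.3 -1038.2
4 4  -1064.9 -1386.2  -743.6
5 5  -1124.4 -1439.6  -809.3
6 6  -1118.8 -1429.8  -807.8
7 7   -655.3  -965.7  -344.9
```

Negative values mean higher Gini (more unequal MVPA bout lengths) is
associated with *faster* same-day RT; the association is strongest midweek
and weakest on Sunday (the planted Sunday effect is zero; cyclic smoothing
pulls the Sunday estimate partway toward its weekday neighbours —
`plot(fit)` shows the band). In this run 3.6 % of person-days failed the
wear/EMA validity rules, matching the exclusion rates such protocols
report. `mean_abs_effect(fit, "gini_MVPA")` summarizes the curve height
(933 ms per unit Gini here).

One call runs everything (six models + manifest):
`run_pipeline(pipeline_config(simulate = list(n_subjects = 87), seed = 1))`,
and `simulate_power(power_config())` reproduces the power table for the
87 × 14 design.

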