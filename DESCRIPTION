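Package: boutcog
Title: Day-of-Week Varying-Coefficient Analysis of Activity Bout
    Distributions and Ambulatory Cognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Segments accelerometer event streams into sedentary, light and
    moderate-to-vigorous activity bouts (one-minute floor); summarizes each
    day-of-week distribution of bout lengths with the alpha (power-law tail)
    and Gini (inequality) indices; aggregates ecological momentary
    assessment symbol-search trials into day-level cognitive outcomes;
    applies valid-day quality control; and fits day-of-week
    varying-coefficient regressions with cyclic penalized splines, subject
    random intercepts, pointwise Bayesian intervals and Wald-type curve
    tests. Includes a synthetic cohort generator with planted effects and a
    Monte Carlo power study for multilevel daily-diary designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    lme4,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
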