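test_that("gini_index matches hand-computed and double-loop values", {
  expect_equal(gini_index(c(5, 5, 5, 5)), 0)
  expect_equal(gini_index(c(1, 4)), 0.3)          # sum |xi-xj| = 6, denom 2*2*5
  expect_equal(gini_index(c(1, 1, 8)), 7 / 15)    # sum = 28, denom 2*3*10
  expect_true(is.na(gini_index(numeric(0))))
  expect_error(gini_index(c(1, 0)), "> 0")
  for (case in list(c(2, 2), c(1, 2, 3, 4), exp(rnorm(17)))) {
    expect_equal(gini_index(case), gini_loop(case), tolerance = 1e-12)
  }
})

test_that("sorted-form Gini agrees with the double-loop definition on random samples", {
  set.seed(401)
  for (i in 1:200) {
    n <- sample(1:60, 1)
    x <- 1 + rexp(n, rate = 1 / sample(c(0.5, 2, 10), 1))
    expect_equal(gini_index(x), gini_loop(x), tolerance = 1e-10)
  }
})

test_that("Gini is scale invariant and bounded by 1 - 1/n", {
  set.seed(402)
  for (i in 1:100) {
    n <- sample(2:40, 1)
    x <- rpowerlaw(n, tail = runif(1, 1.5, 4))
    g <- gini_index(x)
    expect_gte(g, 0)
    expect_lte(g, 1 - 1 / n + 1e-12)
    cc <- runif(1, 1e-3, 1e3)
    expect_equal(gini_index(cc * x), g, tolerance = 1e-12)
  }
})

test_that("alpha_index matches direct evaluation and flags degenerate samples", {
  expect_equal(alpha_index(exp(1)), 2)                   # M = 1
  expect_equal(alpha_index(c(1, exp(2), 1)), 2.5)        # M = 2/3
  expect_true(is.na(alpha_index(c(1, 1, 1))))            # all at the floor
  expect_true(is.na(alpha_index(numeric(0))))
  expect_error(alpha_index(c(0.5, 2)), "floor")
  # joint scale invariance: scaling lengths and the floor together
  set.seed(403)
  x <- rpowerlaw(50, 2.5)
  expect_equal(alpha_index(3 * x, x_min = 3), alpha_index(x), tolerance = 1e-12)
})

test_that("dow_indices pools valid same-weekday dates and leaves empty cells missing", {
  # two Mondays with identical bout multisets; one Tuesday with no MVPA
  bouts <- data.frame(
    subject_id = "A",
    date = as.Date(c("2024-01-08", "2024-01-08", "2024-01-15", "2024-01-15",
                     "2024-01-09", "2024-01-09")),
    cls = c("SED", "SED", "SED", "SED", "SED", "LPA"),
    length_min = c(2, 6, 2, 6, 3, 4))
  bouts$dow <- boutcog:::dow_of(bouts$date)
  valid <- data.frame(subject_id = "A",
                      date = as.Date(c("2024-01-08", "2024-01-15", "2024-01-09")))
  ix <- dow_indices(bouts, valid)

  mon_sed <- ix[ix$dow == 2 & ix$cls == "SED", ]
  # duplication invariance of the Gini: pooled {2,6,2,6} equals one day's {2,6}
  expect_equal(mon_sed$gini, gini_loop(c(2, 6)))
  expect_equal(mon_sed$n_bouts_per_day, 2)
  expect_equal(mon_sed$n_days_contributing, 2)

  tue_mvpa <- ix[ix$dow == 3 & ix$cls == "MVPA", ]
  expect_true(is.na(tue_mvpa$alpha) && is.na(tue_mvpa$gini))
  expect_equal(tue_mvpa$n_bouts_per_day, 0)

  # invalidating one Monday leaves the other Monday's sample alone
  ix2 <- dow_indices(bouts, valid[valid$date != as.Date("2024-01-15"), ])
  mon2 <- ix2[ix2$dow == 2 & ix2$cls == "SED", ]
  expect_equal(mon2$gini, gini_loop(c(2, 6)))
  expect_equal(mon2$n_days_contributing, 1)
})

test_that("per_day_mean aggregation averages per-date indices", {
  bouts <- data.frame(
    subject_id = "A",
    date = as.Date(c("2024-01-08", "2024-01-08", "2024-01-15", "2024-01-15", "2024-01-15")),
    cls = "SED",
    length_min = c(2, 6, 1, 1, 10))
  bouts$dow <- boutcog:::dow_of(bouts$date)
  valid <- data.frame(subject_id = "A", date = unique(bouts$date))
  ix <- dow_indices(bouts, valid, aggregation = "per_day_mean")
  sed <- ix[ix$cls == "SED", ]
  expect_equal(sed$gini, mean(c(gini_loop(c(2, 6)), gini_loop(c(1, 1, 10)))))
  expect_equal(sed$n_bouts_per_day, 5 / 2)
})

test_that("index_report keeps stable columns, missingness, and row counts", {
  set.seed(404)
  cfg <- sim_config(n_subjects = 4, seed = 404)
  coh <- generate_cohort(cfg)
  ex <- summarize_days(coh$events)
  valid <- unique(ex$bouts[, c("subject_id", "date")])
  ix <- dow_indices(ex$bouts, valid)
  rep <- index_report(ix)
  # one row per (subject, dow, cls); brute-force group-by count
  expect_equal(nrow(rep), nrow(unique(ix[, c("subject_id", "dow", "cls")])))
  expect_lte(nrow(rep), 4 * 7 * 3)
  path <- tempfile(fileext = ".csv")
  index_report(ix, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(rep))
  expect_equal(is.na(back$alpha), is.na(rep$alpha))
})
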