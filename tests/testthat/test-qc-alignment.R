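mk_day_summary <- function(wear, dates = as.Date("2024-01-08") + seq_along(wear) - 1,
                           subject = "A") {
  data.frame(subject_id = subject, date = dates, wear_hours = wear)
}
mk_cog <- function(sessions, dates, subject = "A") {
  data.frame(subject_id = subject, date = dates,
             n_complete_sessions = sessions,
             median_rt = ifelse(sessions > 0, 2300, NA),
             mean_correct = ifelse(sessions > 0, 17.5, NA))
}

test_that("valid-day rules follow the 10 h / 1 session boundaries with low_wear precedence", {
  ds <- mk_day_summary(c(9.9, 12, 10.0, 8))
  cg <- mk_cog(c(2, 0, 1, 0), ds$date)
  vd <- flag_valid_days(ds, cg)
  expect_equal(vd$valid, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(vd$exclusion_reason, c("low_wear", "no_ema", "none", "low_wear"))
})

test_that("days seen only in cognition count as zero wear", {
  ds <- mk_day_summary(12, dates = as.Date("2024-01-08"))
  cg <- mk_cog(c(2, 3), as.Date(c("2024-01-08", "2024-01-09")))
  vd <- flag_valid_days(ds, cg)
  d2 <- vd[vd$date == as.Date("2024-01-09"), ]
  expect_equal(d2$wear_hours, 0)
  expect_equal(d2$exclusion_reason, "low_wear")
})

test_that("the analysis table averages valid same-weekday dates and drops absent cells", {
  dates <- as.Date("2024-01-07") + 0:13          # Sunday start, two weeks
  ds <- mk_day_summary(rep(12, 14), dates)
  cg <- mk_cog(rep(2, 14), dates)
  cg$median_rt <- ifelse(boutcog:::dow_of(dates) == 2, c(2200, 2400), 2300)
  vd <- flag_valid_days(ds, cg)
  vd$valid[boutcog:::dow_of(vd$date) == 1] <- FALSE       # no valid Sundays
  vd$exclusion_reason[boutcog:::dow_of(vd$date) == 1] <- "low_wear"
  bouts <- data.frame(subject_id = "A", date = rep(dates, each = 2),
                      cls = "SED", length_min = rep(c(2, 7), 14))
  bouts$dow <- boutcog:::dow_of(bouts$date)
  ix <- dow_indices(bouts, vd[vd$valid, c("subject_id", "date")])
  dem <- data.frame(subject_id = "A", age = 70, sex = 1, education = "college")
  tab <- build_analysis_table(vd, cg, ix, dem)
  expect_equal(tab$median_rt[tab$dow == 2], mean(c(2200, 2400)))
  expect_false(1 %in% tab$dow)                    # no Sunday row
  expect_equal(nrow(tab), 6)
  expect_equal(tab$edu_college[1], 1)
  expect_equal(tab$edu_advanced[1], 0)

  # permuting input rows leaves the table unchanged
  tab2 <- build_analysis_table(vd[sample(nrow(vd)), ], cg[sample(nrow(cg)), ],
                               ix[sample(nrow(ix)), ], dem)
  expect_equal(tab2, tab)

  expect_error(build_analysis_table(vd, cg, ix,
                                    dem[dem$subject_id != "A", ]),
               "demographics")
})

test_that("a fully compliant synthetic cohort yields seven rows per subject", {
  cfg <- sim_config(n_subjects = 4, compliance = 1, incomplete_rate = 0,
                    low_wear_rate = 0, seed = 21)
  coh <- generate_cohort(cfg)
  ex <- summarize_days(coh$events)
  cg <- cognitive_days(coh$trials)
  vd <- flag_valid_days(ex$day_summary, cg)
  expect_true(all(vd$valid))
  ix <- dow_indices(ex$bouts, vd[vd$valid, c("subject_id", "date")])
  tab <- build_analysis_table(vd, cg, ix, coh$demographics)
  expect_equal(as.integer(table(tab$subject_id)), rep(7L, 4))
  expect_true(all(tab$n_days == 2))
})

test_that("exclusion reports count person-days by reason", {
  ds <- mk_day_summary(rep(12, 10))
  cg <- mk_cog(rep(1, 10), ds$date)
  vd <- flag_valid_days(ds, cg)
  er <- exclusion_report(vd)
  expect_equal(er$pct_excluded, 0)

  ds$wear_hours[1:5] <- 5
  vd <- flag_valid_days(rbind(ds, mk_day_summary(rep(12, 90),
                                                 dates = as.Date("2024-03-01") + 0:89)),
                        rbind(cg, mk_cog(rep(1, 90), as.Date("2024-03-01") + 0:89)))
  er <- exclusion_report(vd)
  expect_equal(er$n_person_days, 100)
  expect_equal(er$pct_excluded, 5.0)
  expect_equal(sum(er$by_reason$n), er$n_person_days)  # recount oracle
  expect_equal(er$by_reason$n[er$by_reason$reason == "low_wear"], 5)
})
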