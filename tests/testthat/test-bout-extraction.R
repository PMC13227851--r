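test_that("classification follows the MET/posture cut-points", {
  expect_equal(classify_event(1.0, "seated_reclined"), "SED")
  expect_equal(classify_event(1.24, "seated_reclined"), "SED")
  expect_equal(classify_event(1.25, "seated_reclined"), "LPA")  # boundary: LPA
  expect_equal(classify_event(2.99, "stepping"), "LPA")
  expect_equal(classify_event(3.0, "stepping"), "MVPA")         # boundary: MVPA
  expect_equal(classify_event(1.0, "standing"), "OTHER")        # quiet standing
  expect_equal(classify_event(c(0.9, 5), c("seated_reclined", "stepping")),
               c("SED", "MVPA"))
  expect_error(classify_event(-1, "standing"), ">= 0")
  expect_error(classify_event(1, "sitting"), "posture")
})

test_that("the one-minute floor, contiguity merge, and gap breaking behave as specified", {
  # 50 s of stepping at 3.5 METs: no MVPA bout survives the floor
  ev <- mk_events(50, 3.5, "stepping")
  b <- extract_bouts(ev)
  expect_equal(sum(b$cls == "MVPA"), 0)
  expect_equal(b$cls, "OTHER")

  # 30 min seated at 1.0 MET: one SED bout of 30 minutes
  b <- extract_bouts(mk_events(1800, 1.0, "seated_reclined"))
  expect_equal(b$cls, "SED")
  expect_equal(b$length_min, 30)

  # contiguous same-class events merge: 10 min + 5 min seated -> 15 min
  b <- extract_bouts(mk_events(c(600, 300), c(1.0, 1.1), "seated_reclined"))
  expect_equal(nrow(b), 1)
  expect_equal(b$length_min, 15)

  # a gap over the 1 s tolerance breaks the bout
  b <- extract_bouts(mk_events(c(600, 300), 1.0, "seated_reclined", gaps_s = c(5, 0)))
  expect_equal(nrow(b), 2)
  expect_equal(b$length_min, c(10, 5))

  # class change breaks the run even with no gap
  b <- extract_bouts(mk_events(c(300, 300), c(1.0, 2.0),
                               c("seated_reclined", "stepping")))
  expect_equal(b$cls, c("SED", "LPA"))
})

test_that("overlapping events are rejected with the offending pair named", {
  ev <- mk_events(c(600, 600), 1.0, "seated_reclined")
  ev$start[2] <- ev$start[1] + 300
  expect_error(extract_bouts(ev), "overlap.*T01")
})

test_that("wear time is the event coverage clipped to the wake window", {
  day <- as.Date("2024-01-08")
  # events tiling the 16 h window
  ev <- mk_events(rep(3600, 16), 1.0, "seated_reclined")
  expect_equal(wear_time(ev, day), 16)
  # empty stream
  expect_equal(wear_time(ev[0, ], day), 0)
  # 12 h of coverage with a 2 h hole, against the sort-and-merge oracle
  ev2 <- mk_events(rep(3600, 12), 1.0, "seated_reclined",
                   gaps_s = c(rep(0, 5), 7200, rep(0, 6)))
  w0 <- as.numeric(as.POSIXct("2024-01-08 06:00:00", tz = ""))
  st <- as.numeric(ev2$start)
  expect_equal(wear_time(ev2, day),
               union_hours(st, st + ev2$duration_s, w0, w0 + 16 * 3600))
  expect_equal(wear_time(ev2, day), 12)
})

test_that("day summaries count bouts per class and are order invariant", {
  ev <- rbind(mk_events(rep(300, 6), rep(c(1.0, 2.0), 3),
                        rep(c("seated_reclined", "stepping"), 3)),
              mk_events(120, 3.5, "stepping",
                        origin = as.POSIXct("2024-01-08 12:00:00", tz = "")))
  b <- extract_bouts(ev)
  ds <- summarize_day(b, ev, "2024-01-08")
  # brute-force recount from the bout table
  expect_equal(ds$n_SED, sum(b$cls == "SED"))
  expect_equal(ds$n_LPA, sum(b$cls == "LPA"))
  expect_equal(ds$n_MVPA, sum(b$cls == "MVPA"))
  expect_equal(ds$n_SED, 3)
  expect_equal(ds$n_LPA, 3)
  expect_equal(ds$n_MVPA, 1)
  perm <- b[sample(nrow(b)), ]
  expect_equal(summarize_day(perm, ev, "2024-01-08")[, -1],
               ds[, -1])
})

test_that("extraction is idempotent on the event projection of its own bouts", {
  set.seed(77)
  day <- generate_day_events("P1", "2024-01-08", sim_config(n_subjects = 1), seed = 77)
  b1 <- extract_bouts(day$events)
  met_of <- c(SED = 1.0, LPA = 2.0, MVPA = 3.5, OTHER = 1.0)
  posture_of <- c(SED = "seated_reclined", LPA = "stepping",
                  MVPA = "stepping", OTHER = "standing")
  proj <- data.frame(subject_id = b1$subject_id, start = b1$start,
                     duration_s = b1$length_min * 60,
                     posture = unname(posture_of[b1$cls]),
                     met = unname(met_of[b1$cls]))
  b2 <- extract_bouts(proj)
  expect_equal(b2$cls, b1$cls)
  expect_equal(b2$length_min, b1$length_min, tolerance = 1e-9)
})

test_that("bout and OTHER durations conserve wear time on a generated day", {
  set.seed(78)
  day <- generate_day_events("P1", "2024-01-08", sim_config(n_subjects = 1), seed = 78)
  b <- extract_bouts(day$events)
  wear <- wear_time(day$events, "2024-01-08")
  expect_equal(sum(b$length_min) / 60, wear, tolerance = 1 / 3600)
  expect_false(any(b$cls %in% c("SED", "LPA", "MVPA") & b$length_min < 1))
})

test_that("event readers validate dialects and map activPAL codes", {
  ev <- mk_events(c(600, 300), c(1.0, 3.2), c("seated_reclined", "stepping"))
  ev$start <- format(ev$start, "%Y-%m-%d %H:%M:%S")
  path <- tempfile(fileext = ".csv")
  write.csv(ev, path, row.names = FALSE)
  back <- read_events(path)
  expect_equal(back$met, ev$met)

  ap <- data.frame(subject_id = "T01", start = ev$start, duration_s = ev$duration_s,
                   activity = c(0, 2), met = ev$met)
  write.csv(ap, path, row.names = FALSE)
  back2 <- read_events(path, format = "activpal")
  expect_equal(back2$posture, c("seated_reclined", "stepping"))

  bad <- ev; bad$met[1] <- -2
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_events(path), "line 2")
})
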