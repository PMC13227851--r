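# Accelerometer event stream -> classified activity bouts and per-day wear
# summaries. Events are contiguous posture/MET records; a bout is a maximal
# run of temporally contiguous events sharing one intensity class, kept only
# if it lasts at least the one-minute recordable floor.

BOUT_CLASSES <- c("SED", "LPA", "MVPA")
POSTURES <- c("seated_reclined", "standing", "stepping")

#' Classify an event by MET value and posture
#'
#' Sedentary: < 1.25 METs in a seated or reclined posture. LPA: 1.25-2.99
#' METs (any posture). MVPA: >= 3 METs. Anything else (e.g. quiet standing
#' below 1.25 METs) is \code{OTHER} and never contributes to the indices.
#'
#' @param met metabolic equivalents (>= 0); vectorized
#' @param posture one of \code{"seated_reclined"}, \code{"standing"},
#'   \code{"stepping"}; vectorized
#' @return character vector: \code{"SED"}, \code{"LPA"}, \code{"MVPA"} or
#'   \code{"OTHER"}
#' @export
classify_event <- function(met, posture) {
  if (any(!is.finite(met)) || any(met < 0))
    stop_input("classify_event: MET values must be finite and >= 0")
  bad <- !posture %in% POSTURES
  if (any(bad))
    stop_input("classify_event: unknown posture '%s'", posture[which(bad)[1]])
  out <- rep("OTHER", length(met))
  out[met >= 3] <- "MVPA"
  out[met >= 1.25 & met < 3] <- "LPA"
  out[met < 1.25 & posture == "seated_reclined"] <- "SED"
  out
}

#' Extract classified activity bouts from an event stream
#'
#' Merges maximal runs of temporally contiguous events sharing one class into
#' candidate bouts; two events are contiguous when the gap between them is at
#' most \code{gap_tol_s} seconds (event files are nominally gapless; the
#' tolerance absorbs rounding). A larger gap always breaks a bout. Candidate
#' SED/LPA/MVPA bouts shorter than \code{min_bout_min} minutes are
#' reclassified as \code{OTHER}; \code{OTHER} segments are retained (they
#' carry wear time) but never feed the distribution indices. A bout belongs
#' to the calendar date on which it starts; bouts spanning midnight are not
#' split.
#'
#' @param events data.frame with columns \code{subject_id}, \code{start}
#'   (POSIXct or ISO 8601 string, local clock time), \code{duration_s},
#'   \code{posture}, \code{met}; one subject, or several (grouped internally)
#' @param min_bout_min minimum bout duration in minutes (default 1)
#' @param gap_tol_s contiguity tolerance in seconds (default 1)
#' @return data.frame of bouts: \code{subject_id, date, dow, cls, start,
#'   length_min}, with \code{dow} coded 1 = Sunday ... 7 = Saturday
#' @export
extract_bouts <- function(events, min_bout_min = 1, gap_tol_s = 1) {
  ev <- data.table::as.data.table(events)
  req <- c("subject_id", "start", "duration_s", "posture", "met")
  missing_cols <- setdiff(req, names(ev))
  if (length(missing_cols))
    stop_input("extract_bouts: events lack columns: %s", paste(missing_cols, collapse = ", "))
  if (any(!is.finite(ev$duration_s)) || any(ev$duration_s <= 0))
    stop_input("extract_bouts: event durations must be > 0")
  ev[, start := parse_time(start)]
  ev[, cls := classify_event(met, posture)]
  data.table::setorder(ev, subject_id, start)
  ev[, end := as.numeric(start) + duration_s]
  ev[, gap := as.numeric(start) - data.table::shift(end), by = subject_id]

  # timestamps round-trip through millisecond-precision text, so only gaps
  # more negative than 5 ms count as genuine overlap
  overlap <- which(!is.na(ev$gap) & ev$gap < -5e-3)
  if (length(overlap)) {
    i <- overlap[1]
    stop_input("extract_bouts: overlapping events for subject %s at %s (previous event ends %.1f s later)",
               ev$subject_id[i], format(ev$start[i]), -ev$gap[i])
  }
  ev[, new_run := is.na(gap) | gap > gap_tol_s | cls != data.table::shift(cls, fill = "")]
  ev[is.na(new_run), new_run := TRUE]
  ev[, run := cumsum(new_run), by = subject_id]

  bouts <- ev[, .(start = start[1], length_min = sum(duration_s) / 60, cls = cls[1]),
              by = .(subject_id, run)]
  bouts[cls %in% BOUT_CLASSES & length_min < min_bout_min, cls := "OTHER"]
  bouts[, date := as.Date(format(start, "%Y-%m-%d"))]
  bouts[, dow := dow_of(date)]
  bouts[, run := NULL]
  data.table::setcolorder(bouts, c("subject_id", "date", "dow", "cls", "start", "length_min"))
  as.data.frame(bouts)
}

#' Wear time on a date within a wake window
#'
#' Total event-covered time intersected with the wake window
#' \code{[wake_start, wake_end)} (clock hours) of the given calendar date,
#' in hours. Events are assumed non-overlapping, so the union length is the
#' sum of clipped durations.
#'
#' @param events event data.frame (see [extract_bouts()]); may span subjects
#'   only if all belong to the same person-day of interest
#' @param date calendar date (Date or string)
#' @param wake_window numeric length-2: start and end clock hours, default
#'   \code{c(6, 22)}
#' @return wear time in hours
#' @export
wear_time <- function(events, date, wake_window = c(6, 22)) {
  stopifnot(length(wake_window) == 2L, wake_window[2] > wake_window[1])
  if (!nrow(events)) return(0)
  st <- as.numeric(parse_time(events$start))
  en <- st + events$duration_s
  day0 <- as.numeric(as.POSIXct(paste(as.Date(date), "00:00:00"), tz = ""))
  w0 <- day0 + wake_window[1] * 3600
  w1 <- day0 + wake_window[2] * 3600
  covered <- pmin(en, w1) - pmax(st, w0)
  sum(pmax(covered, 0)) / 3600
}

#' Summarize one subject-day
#'
#' Per-class bout counts (the N covariate at day grain) and wear hours.
#'
#' @param bouts bout table for the subject (from [extract_bouts()])
#' @param events event table for the subject
#' @param date calendar date
#' @param wake_window wake window passed to [wear_time()]
#' @return one-row data.frame: \code{subject_id, date, dow, wear_hours,
#'   n_SED, n_LPA, n_MVPA}
#' @export
summarize_day <- function(bouts, events, date, wake_window = c(6, 22)) {
  date <- as.Date(date)
  b <- bouts[as.Date(bouts$date) == date, , drop = FALSE]
  sid <- unique(c(b$subject_id, events$subject_id))
  if (length(sid) > 1L) stop_input("summarize_day: inputs must come from one subject")
  counts <- vapply(BOUT_CLASSES, function(k) sum(b$cls == k), numeric(1))
  data.frame(subject_id = if (length(sid)) sid else NA_character_,
             date = date, dow = dow_of(date),
             wear_hours = wear_time(events, date, wake_window),
             n_SED = counts[["SED"]], n_LPA = counts[["LPA"]], n_MVPA = counts[["MVPA"]])
}

#' Summarize all subject-days in an event table
#'
#' Convenience wrapper: runs [extract_bouts()] once and [summarize_day()] for
#' every (subject, date) with any event coverage.
#'
#' @inheritParams extract_bouts
#' @param wake_window wake window (clock hours)
#' @return list with \code{bouts} and \code{day_summary} data.frames
#' @export
summarize_days <- function(events, min_bout_min = 1, gap_tol_s = 1, wake_window = c(6, 22)) {
  ev <- data.table::as.data.table(events)
  ev[, start := parse_time(start)]
  bouts <- extract_bouts(ev, min_bout_min, gap_tol_s)
  ev[, date := as.Date(format(start, "%Y-%m-%d"))]
  keys <- unique(ev[, .(subject_id, date)])
  bt <- data.table::as.data.table(bouts)
  counts <- bt[cls %in% BOUT_CLASSES,
               .N, by = .(subject_id, date, cls)]
  wide <- data.table::dcast(counts, subject_id + date ~ cls, value.var = "N", fill = 0L)
  for (k in BOUT_CLASSES) if (!k %in% names(wide)) wide[, (k) := 0L]
  ds <- wide[keys, on = c("subject_id", "date")]
  for (k in BOUT_CLASSES) ds[is.na(get(k)), (k) := 0L]
  # wear: per subject-day clipped coverage
  day0 <- as.numeric(as.POSIXct(paste(ds$date, "00:00:00"), tz = ""))
  ev[, snum := as.numeric(start)]
  ev[, enum := snum + duration_s]
  evd <- ev[, .(subject_id, date, snum, enum)]
  dsk <- ds[, .(subject_id, date)]
  dsk[, w0 := day0 + wake_window[1] * 3600]
  dsk[, w1 := day0 + wake_window[2] * 3600]
  evj <- evd[dsk, on = c("subject_id", "date")]
  evj[, cov := pmax(pmin(enum, w1) - pmax(snum, w0), 0)]
  wear <- evj[, .(wear_hours = sum(cov) / 3600), by = .(subject_id, date)]
  ds <- wear[ds, on = c("subject_id", "date")]
  ds[, dow := dow_of(date)]
  data.table::setnames(ds, BOUT_CLASSES, paste0("n_", BOUT_CLASSES))
  data.table::setcolorder(ds, c("subject_id", "date", "dow", "wear_hours",
                                "n_SED", "n_LPA", "n_MVPA"))
  data.table::setorder(ds, subject_id, date)
  list(bouts = bouts, day_summary = as.data.frame(ds))
}

#' Read an accelerometer event CSV
#'
#' Native dialect: \code{subject_id, start (ISO 8601), duration_s, posture,
#' met}. The \code{"activpal"} dialect instead carries an integer activity
#' code (0 = sedentary, 1 = standing, 2 = stepping) in a column named
#' \code{activity}, which is mapped onto the posture vocabulary.
#'
#' @param path CSV file path
#' @param format \code{"native"} or \code{"activpal"}
#' @return validated event data.frame
#' @export
read_events <- function(path, format = c("native", "activpal")) {
  format <- match.arg(format)
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "activpal") {
    req <- c("subject_id", "start", "duration_s", "activity", "met")
    check_columns(ev, req, "read_events")
    map <- c(`0` = "seated_reclined", `1` = "standing", `2` = "stepping")
    ev$posture <- unname(map[as.character(ev$activity)])
    if (anyNA(ev$posture))
      stop_input("read_events: unknown activPAL activity code at line %d",
                 which(is.na(ev$posture))[1] + 1L)
    ev$activity <- NULL
  } else {
    check_columns(ev, c("subject_id", "start", "duration_s", "posture", "met"), "read_events")
  }
  bad <- which(!is.finite(ev$duration_s) | ev$duration_s <= 0 |
                 !is.finite(ev$met) | ev$met < 0 | !ev$posture %in% POSTURES)
  if (length(bad))
    stop_input("read_events: %d malformed row(s), e.g. line %s",
               length(bad), paste(utils::head(bad + 1L, 5), collapse = ", "))
  ev
}

check_columns <- function(df, req, fn) {
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop_input("%s: missing required column(s): %s", fn, paste(missing_cols, collapse = ", "))
  invisible(TRUE)
}

parse_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, tz = "", tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(out) && !anyNA(x)) stop_input("unparseable timestamp, e.g. '%s'", x[which(is.na(out))[1]])
  out
}
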