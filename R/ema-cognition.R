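# EMA symbol-search aggregation: trial records -> session summaries ->
# day-level cognitive outcomes (median RT of accurate trials; mean number of
# correct trials).

#' Summarize one symbol-search session
#'
#' @param trials data.frame of trial records sharing one \code{subject_id}
#'   and \code{session_start}: columns \code{trial_index}, \code{rt_ms},
#'   \code{correct} (0/1 or logical)
#' @param trials_per_session number of trials in a complete session
#'   (default 18)
#' @return one-row data.frame: \code{subject_id, session_start, date,
#'   n_trials, n_correct, median_rt_accurate, complete}. The median RT is
#'   \code{NA} when no trial was accurate; even-count medians take the
#'   midpoint of the two central values (the default \code{median}).
#' @export
summarize_session <- function(trials, trials_per_session = 18) {
  if (length(unique(trials$subject_id)) > 1L ||
      length(unique(as.character(trials$session_start))) > 1L)
    stop_input("summarize_session: trials must share one subject and session")
  if (anyDuplicated(trials$trial_index))
    stop_input("summarize_session: duplicate trial_index %s",
               trials$trial_index[duplicated(trials$trial_index)][1])
  correct <- as.logical(trials$correct)
  acc_rt <- trials$rt_ms[correct]
  st <- parse_time(trials$session_start[1])
  data.frame(subject_id = trials$subject_id[1],
             session_start = st,
             date = as.Date(format(st, "%Y-%m-%d")),
             n_trials = nrow(trials),
             n_correct = sum(correct),
             median_rt_accurate = if (length(acc_rt)) stats::median(acc_rt) else NA_real_,
             complete = nrow(trials) == trials_per_session)
}

#' Summarize every session in a trial table
#'
#' @param trials trial table (see [read_trials()] for the dialect)
#' @param trials_per_session number of trials in a complete session
#' @return data.frame with one row per (subject, session)
#' @export
summarize_sessions <- function(trials, trials_per_session = 18) {
  tr <- data.table::as.data.table(trials)
  tr[, session_start := parse_time(session_start)]
  if (nrow(unique(tr[, .(subject_id, session_start, trial_index)])) != nrow(tr))
    stop_input("summarize_sessions: duplicate trial_index within a session")
  out <- tr[, {
    correct <- as.logical(correct)
    acc <- rt_ms[correct]
    .(date = as.Date(format(session_start[1], "%Y-%m-%d")),
      n_trials = .N, n_correct = sum(correct),
      median_rt_accurate = if (length(acc)) stats::median(acc) else NA_real_,
      complete = .N == trials_per_session)
  }, by = .(subject_id, session_start)]
  data.table::setorder(out, subject_id, session_start)
  as.data.frame(out)
}

#' Aggregate sessions to a day-level cognitive outcome
#'
#' Only complete sessions count. The day RT is, by default, the median of the
#' *pooled* accurate-trial RTs across the day's complete sessions
#' (\code{rt_mode = "pooled"}); \code{rt_mode = "session_median"} instead
#' averages the per-session medians. \code{mean_correct} is the mean of the
#' per-session correct counts. A complete session with zero accurate trials
#' still validates the day but contributes no RTs.
#'
#' @param sessions session summaries for one subject-date
#'   (from [summarize_session()]); for \code{rt_mode = "pooled"} supply
#'   \code{trials} too
#' @param trials the day's trial records (needed for pooled RT)
#' @param rt_mode \code{"pooled"} (default) or \code{"session_median"}
#' @return one-row data.frame: \code{subject_id, date, dow,
#'   n_complete_sessions, median_rt, mean_correct}
#' @export
aggregate_day <- function(sessions, trials = NULL,
                          rt_mode = c("pooled", "session_median")) {
  rt_mode <- match.arg(rt_mode)
  if (length(unique(sessions$subject_id)) > 1L ||
      length(unique(as.character(sessions$date))) > 1L)
    stop_input("aggregate_day: sessions must share one subject and date")
  comp <- sessions[sessions$complete, , drop = FALSE]
  date <- as.Date(sessions$date[1])
  if (!nrow(comp)) {
    return(data.frame(subject_id = sessions$subject_id[1], date = date,
                      dow = dow_of(date), n_complete_sessions = 0L,
                      median_rt = NA_real_, mean_correct = NA_real_))
  }
  if (rt_mode == "pooled") {
    if (is.null(trials)) stop_input("aggregate_day: pooled RT needs the trial records")
    tr <- trials
    tr$session_start <- parse_time(tr$session_start)
    keep <- tr$session_start %in% comp$session_start & as.logical(tr$correct)
    rts <- tr$rt_ms[keep]
    med <- if (length(rts)) stats::median(rts) else NA_real_
  } else {
    meds <- comp$median_rt_accurate[!is.na(comp$median_rt_accurate)]
    med <- if (length(meds)) mean(meds) else NA_real_
  }
  data.frame(subject_id = sessions$subject_id[1], date = date,
             dow = dow_of(date), n_complete_sessions = nrow(comp),
             median_rt = med, mean_correct = mean(comp$n_correct))
}

#' Day-level cognitive outcomes for a whole trial table
#'
#' @param trials trial table
#' @param trials_per_session complete-session size
#' @param rt_mode see [aggregate_day()]
#' @return data.frame with one row per (subject, date):
#'   \code{subject_id, date, dow, n_complete_sessions, median_rt,
#'   mean_correct}
#' @export
cognitive_days <- function(trials, trials_per_session = 18,
                           rt_mode = c("pooled", "session_median")) {
  rt_mode <- match.arg(rt_mode)
  tr <- data.table::as.data.table(trials)
  tr[, session_start := parse_time(session_start)]
  ses <- data.table::as.data.table(summarize_sessions(tr, trials_per_session))
  tr[, date := as.Date(format(session_start, "%Y-%m-%d"))]
  comp <- ses[complete == TRUE]
  if (rt_mode == "pooled") {
    trc <- tr[comp[, .(subject_id, session_start)], on = c("subject_id", "session_start")]
    rtday <- trc[as.logical(correct), .(median_rt = stats::median(rt_ms)), by = .(subject_id, date)]
  } else {
    rtday <- comp[!is.na(median_rt_accurate),
                  .(median_rt = mean(median_rt_accurate)), by = .(subject_id, date)]
  }
  accday <- comp[, .(n_complete_sessions = .N, mean_correct = mean(n_correct)),
                 by = .(subject_id, date)]
  alldays <- unique(ses[, .(subject_id, date)])
  out <- accday[alldays, on = c("subject_id", "date")]
  out <- rtday[out, on = c("subject_id", "date")]
  out[is.na(n_complete_sessions), n_complete_sessions := 0L]
  out[, dow := dow_of(date)]
  data.table::setcolorder(out, c("subject_id", "date", "dow",
                                 "n_complete_sessions", "median_rt", "mean_correct"))
  data.table::setorder(out, subject_id, date)
  as.data.frame(out)
}

#' Read an EMA trial CSV
#'
#' Dialect: \code{subject_id, session_start (ISO 8601), trial_index, rt_ms,
#' correct} with \code{correct} in \{0, 1\}. Malformed rows are rejected with
#' their file line numbers; an empty file with a header yields an empty
#' table.
#'
#' @param path CSV file path
#' @return validated trial data.frame
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(tr, c("subject_id", "session_start", "trial_index", "rt_ms", "correct"),
                "read_trials")
  if (!nrow(tr)) return(tr)
  bad <- which(!is.finite(tr$rt_ms) | tr$rt_ms <= 0 |
                 !tr$correct %in% c(0, 1, TRUE, FALSE) |
                 !is.finite(tr$trial_index) | tr$trial_index < 1)
  if (length(bad))
    stop_input("read_trials: %d malformed row(s) at line(s) %s",
               length(bad), paste(utils::head(bad + 1L, 10), collapse = ", "))
  tr
}
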