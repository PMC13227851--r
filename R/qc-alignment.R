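# Valid-day rules and assembly of the day-of-week-matched analysis table.
# A protocol day is valid when it has >= 10 h of accelerometer wear during
# waking time AND at least one fully completed symbol-search session.

EDU_LEVELS <- c("high_school", "college", "advanced")

#' Flag valid protocol days
#'
#' One record per protocol day per subject. A day is valid iff
#' \code{wear_hours >= wear_hours_min} and
#' \code{n_complete_sessions >= sessions_min}; when both rules fail the
#' exclusion reason is \code{low_wear} (wear takes precedence). Days present
#' in the cognition table but absent from accelerometry are treated as zero
#' wear and flagged.
#'
#' @param day_summary accelerometer day summaries
#'   (\code{subject_id, date, wear_hours, ...})
#' @param cog_days day-level cognition table from [cognitive_days()]
#' @param wear_hours_min minimum wear (hours), default 10
#' @param sessions_min minimum complete sessions, default 1
#' @param protocol_days optional data.frame \code{subject_id, date} giving
#'   the full protocol grid; defaults to the union of dates seen in either
#'   input
#' @return data.frame: \code{subject_id, date, dow, wear_hours,
#'   n_complete_sessions, valid, exclusion_reason}
#' @export
flag_valid_days <- function(day_summary, cog_days,
                            wear_hours_min = 10, sessions_min = 1,
                            protocol_days = NULL) {
  ds <- data.table::as.data.table(day_summary)[, .(subject_id, date = as.Date(date), wear_hours)]
  cg <- data.table::as.data.table(cog_days)[, .(subject_id, date = as.Date(date), n_complete_sessions)]
  grid <- if (is.null(protocol_days)) {
    unique(rbind(ds[, .(subject_id, date)], cg[, .(subject_id, date)]))
  } else {
    dt <- data.table::as.data.table(protocol_days)
    unique(dt[, .(subject_id, date = as.Date(date))])
  }
  out <- cg[ds[grid, on = c("subject_id", "date")], on = c("subject_id", "date")]
  out[is.na(wear_hours), wear_hours := 0]
  out[is.na(n_complete_sessions), n_complete_sessions := 0L]
  out[, dow := dow_of(date)]
  out[, valid := wear_hours >= wear_hours_min & n_complete_sessions >= sessions_min]
  out[, exclusion_reason := data.table::fifelse(
    valid, "none",
    data.table::fifelse(wear_hours < wear_hours_min, "low_wear", "no_ema"))]
  data.table::setcolorder(out, c("subject_id", "date", "dow", "wear_hours",
                                 "n_complete_sessions", "valid", "exclusion_reason"))
  data.table::setorder(out, subject_id, date)
  as.data.frame(out)
}

#' Assemble the day-of-week-matched analysis table
#'
#' For each (subject, day of week): the outcome is the mean of the day-level
#' outcome over the subject's valid dates on that day of week (at most two in
#' a 14-day protocol); the distribution indices are joined from
#' [dow_indices()] (wide, one column set per class); demographics are
#' constant within subject, with education encoded as two indicator
#' contrasts against the "up to high school" reference. Rows whose index
#' sets are missing for all three classes are dropped. Subjects with
#' outcomes but no demographics raise an error.
#'
#' @param valid_days output of [flag_valid_days()]
#' @param cog_days output of [cognitive_days()]
#' @param indices output of [dow_indices()]
#' @param demographics data.frame \code{subject_id, age, sex, education} with
#'   \code{sex} coded 1 = male / 0 otherwise and \code{education} in
#'   \code{c("high_school", "college", "advanced")}
#' @return analysis data.frame, one row per (subject, dow): outcomes
#'   \code{median_rt}, \code{mean_correct}; per class \code{alpha_<cls>},
#'   \code{gini_<cls>}, \code{nbouts_<cls>}; covariates \code{age, sex,
#'   edu_college, edu_advanced}; bookkeeping \code{n_days}
#' @export
build_analysis_table <- function(valid_days, cog_days, indices, demographics) {
  vd <- data.table::as.data.table(valid_days)
  vd <- vd[valid == TRUE, .(subject_id, date = as.Date(date), vdow = dow)]
  cg <- data.table::as.data.table(cog_days)
  cg[, date := as.Date(date)]
  cj <- cg[vd, on = c("subject_id", "date")]
  ydow <- cj[, .(median_rt = if (all(is.na(median_rt))) NA_real_ else mean(median_rt, na.rm = TRUE),
                 mean_correct = if (all(is.na(mean_correct))) NA_real_ else mean(mean_correct, na.rm = TRUE),
                 n_days = .N),
             by = .(subject_id, dow = vdow)]

  ix <- data.table::as.data.table(indices)
  wide <- data.table::dcast(ix, subject_id + dow ~ cls,
                            value.var = c("alpha", "gini", "n_bouts_per_day"))
  data.table::setnames(wide, sub("^n_bouts_per_day_", "nbouts_", names(wide)))
  tab <- wide[ydow, on = c("subject_id", "dow")]

  idx_cols <- unlist(lapply(c("SED", "LPA", "MVPA"),
                            function(k) paste0(c("alpha_", "gini_"), k)))
  idx_cols <- intersect(idx_cols, names(tab))
  all_missing <- rowSums(!is.na(as.matrix(tab[, ..idx_cols]))) == 0
  tab <- tab[!all_missing]

  dem <- data.table::as.data.table(demographics)
  check_columns(dem, c("subject_id", "age", "sex", "education"), "build_analysis_table")
  orphans <- setdiff(unique(tab$subject_id), dem$subject_id)
  if (length(orphans))
    stop_input("build_analysis_table: no demographics for subject(s): %s",
               paste(utils::head(orphans, 10), collapse = ", "))
  bad_edu <- setdiff(unique(dem$education), EDU_LEVELS)
  if (length(bad_edu))
    stop_input("build_analysis_table: unknown education level(s): %s",
               paste(bad_edu, collapse = ", "))
  dem <- dem[, .(subject_id, age, sex,
                 edu_college = as.integer(education == "college"),
                 edu_advanced = as.integer(education == "advanced"))]
  out <- dem[tab, on = "subject_id"]
  data.table::setcolorder(out, c("subject_id", "dow", "median_rt", "mean_correct", "n_days"))
  data.table::setorder(out, subject_id, dow)
  if (anyDuplicated(out[, .(subject_id, dow)]))
    stop_input("build_analysis_table: duplicate (subject, dow) rows")
  as.data.frame(out)
}

#' Exclusion report
#'
#' Counts and percentages of person-days by exclusion reason. The denominator
#' is the number of protocol person-days (rows of the valid-day table).
#'
#' @param valid_days output of [flag_valid_days()]
#' @return list: \code{n_person_days}, \code{n_valid}, \code{n_excluded},
#'   \code{pct_excluded}, and a \code{by_reason} data.frame
#' @export
exclusion_report <- function(valid_days) {
  vd <- as.data.frame(valid_days)
  n <- nrow(vd)
  tab <- table(factor(vd$exclusion_reason, levels = c("none", "low_wear", "no_ema")))
  by_reason <- data.frame(reason = names(tab), n = as.integer(tab),
                          pct = if (n) 100 * as.integer(tab) / n else 0)
  list(n_person_days = n,
       n_valid = sum(vd$valid),
       n_excluded = n - sum(vd$valid),
       pct_excluded = if (n) 100 * (n - sum(vd$valid)) / n else 0,
       by_reason = by_reason)
}
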