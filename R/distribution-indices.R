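# Bout-length distribution indices: Gini (inequality of bout lengths) and
# alpha (power-law tail exponent), computed per subject, day of week, and
# activity class.

#' Gini index of a bout-length sample
#'
#' Half the relative mean absolute difference of the sample:
#' \deqn{G = \frac{\sum_i \sum_j |x_i - x_j|}{2 n \sum_i x_i}}
#' which coincides with the Lorenz-curve definition. \code{G = 0} means all
#' bouts have equal length; values near 1 mean a few long bouts dominate.
#' The sample version is bounded above by \eqn{1 - 1/n}.
#'
#' Computed via the O(n log n) sorted form
#' \eqn{G = \frac{2 \sum_i i\, x_{(i)}}{n \sum_i x_i} - \frac{n + 1}{n}},
#' algebraically identical to the double loop.
#'
#' @param lengths numeric vector of bout lengths (minutes), all > 0
#' @return Gini index in \code{[0, 1)}, or \code{NA_real_} for an empty sample
#' @seealso [alpha_index()]
#' @export
gini_index <- function(lengths) {
  lengths <- lengths[!is.na(lengths)]
  n <- length(lengths)
  if (n == 0L) return(NA_real_)
  if (any(lengths <= 0)) stop_input("gini_index: all bout lengths must be > 0")
  x <- sort(lengths)
  s <- sum(x)
  if (s == 0) return(NA_real_)
  2 * sum(seq_len(n) * x) / (n * s) - (n + 1) / n
}

#' Alpha index of a bout-length sample
#'
#' Power-law tail summary of the bout-length distribution:
#' \deqn{\alpha = 1 + 1/M, \qquad M = \frac{1}{n}\sum_i \log(x_i / x_{min})}
#' where \code{x_min} is the shortest *recordable* bout length (the 1-minute
#' bout floor by default), fixed by the instrument rather than estimated from
#' the sample. For lengths drawn from a Pareto distribution with scale
#' \code{x_min} this is the maximum-likelihood estimate of the tail exponent.
#' Higher alpha means short bouts predominate and long bouts are rare; lower
#' alpha means activity is consolidated into longer, sustained bouts.
#'
#' When every bout sits exactly at the floor, \eqn{M = 0} and the index is
#' degenerate; it is returned as \code{NA_real_} (rather than \code{Inf}) so
#' that downstream design matrices stay finite.
#'
#' @param lengths numeric vector of bout lengths (minutes)
#' @param x_min shortest recordable bout length (minutes), default 1
#' @return alpha index (> 1), or \code{NA_real_} if the sample is empty or
#'   degenerate
#' @seealso [gini_index()]
#' @export
alpha_index <- function(lengths, x_min = 1) {
  stopifnot(length(x_min) == 1L, is.finite(x_min), x_min > 0)
  lengths <- lengths[!is.na(lengths)]
  n <- length(lengths)
  if (n == 0L) return(NA_real_)
  if (any(lengths < x_min * (1 - 1e-9)))
    stop_input("alpha_index: bout lengths below x_min = %g violate the recordable floor", x_min)
  M <- mean(log(lengths / x_min))
  if (M <= 0) return(NA_real_)
  1 + 1 / M
}

#' Day-of-week bout distribution indices for one or more subjects
#'
#' For each (subject, day of week, class) cell, pools the bout lengths from
#' all of that subject's valid dates falling on that day of week (two dates
#' per weekday in a complete 14-day protocol) and computes the alpha and Gini
#' indices on the pooled sample, together with the mean daily bout count
#' (the N covariate of the regression model). Cells with no bouts of a class
#' get missing indices.
#'
#' @param bouts data.frame of classified bouts with columns \code{subject_id},
#'   \code{date}, \code{dow}, \code{cls}, \code{length_min} (as produced by
#'   [extract_bouts()]); \code{OTHER} segments are ignored
#' @param valid_days data.frame with columns \code{subject_id}, \code{date}
#'   listing the valid protocol days (see [flag_valid_days()])
#' @param x_min shortest recordable bout length in minutes
#' @param aggregation \code{"pool"} (default) pools the lengths from all valid
#'   same-weekday dates before computing the indices; \code{"per_day_mean"}
#'   computes per-date indices and averages the non-missing ones
#' @return data.frame with one row per (subject, dow, cls): columns
#'   \code{subject_id, dow, cls, alpha, gini, n_bouts_per_day,
#'   n_days_contributing}
#' @export
dow_indices <- function(bouts, valid_days, x_min = 1,
                        aggregation = c("pool", "per_day_mean")) {
  aggregation <- match.arg(aggregation)
  bt <- data.table::as.data.table(bouts)
  vd <- data.table::as.data.table(valid_days)[, .(subject_id, date = as.Date(date))]
  if (anyDuplicated(vd)) vd <- unique(vd)
  vd[, dow := dow_of(date)]

  bt <- bt[cls %in% c("SED", "LPA", "MVPA")]
  bt[, date := as.Date(date)]
  bt <- bt[vd, on = c("subject_id", "date"), nomatch = NULL]

  # full grid: every valid (subject, dow) x class, so empty cells are explicit
  grid <- vd[, .(n_days_contributing = .N), by = .(subject_id, dow)]
  grid <- grid[, .(cls = c("SED", "LPA", "MVPA")), by = .(subject_id, dow, n_days_contributing)]

  if (aggregation == "pool") {
    ix <- bt[, .(alpha = alpha_index(length_min, x_min),
                 gini  = gini_index(length_min),
                 n_bouts = .N),
             by = .(subject_id, dow, cls)]
  } else {
    per_day <- bt[, .(alpha = alpha_index(length_min, x_min),
                      gini  = gini_index(length_min),
                      n_bouts = .N),
                  by = .(subject_id, date, dow, cls)]
    ix <- per_day[, .(alpha = if (all(is.na(alpha))) NA_real_ else mean(alpha, na.rm = TRUE),
                      gini  = if (all(is.na(gini)))  NA_real_ else mean(gini, na.rm = TRUE),
                      n_bouts = sum(n_bouts)),
                  by = .(subject_id, dow, cls)]
  }
  out <- ix[grid, on = c("subject_id", "dow", "cls")]
  out[is.na(n_bouts), n_bouts := 0L]
  out[, n_bouts_per_day := n_bouts / n_days_contributing]
  out[, n_bouts := NULL]
  data.table::setcolorder(out, c("subject_id", "dow", "cls", "alpha", "gini",
                                 "n_bouts_per_day", "n_days_contributing"))
  data.table::setorder(out, subject_id, dow, cls)
  as.data.frame(out)
}

#' Tidy index report
#'
#' Stable-column-order view of a [dow_indices()] table, suitable for CSV
#' export; missing indices are kept as explicit \code{NA}.
#'
#' @param indexsets data.frame from [dow_indices()]
#' @param path optional file path; when given the table is also written as CSV
#' @return the tidy data.frame, invisibly when \code{path} is given
#' @export
index_report <- function(indexsets, path = NULL) {
  cols <- c("subject_id", "dow", "cls", "alpha", "gini",
            "n_bouts_per_day", "n_days_contributing")
  missing_cols <- setdiff(cols, names(indexsets))
  if (length(missing_cols))
    stop_input("index_report: missing columns: %s", paste(missing_cols, collapse = ", "))
  out <- indexsets[, cols]
  out <- out[order(out$subject_id, out$dow, out$cls), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    data.table::fwrite(out, path, na = "NA")
    return(invisible(out))
  }
  out
}
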