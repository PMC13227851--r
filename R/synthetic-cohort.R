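# Synthetic cohort generator.
#
# Emulates a 14-day daily-diary protocol in older adults: an accelerometer
# event stream per subject-day (alternating classified bouts with heavy-tailed
# Pareto lengths above the 1-minute recordable floor, interleaved with OTHER
# filler so events tile the wake window), four semi-random EMA prompts per day
# of 18 symbol-search trials each, demographics, and day-level cognitive
# outcomes generated linearly from the *realized* bout-distribution indices
# with planted day-of-week-varying coefficients. The truth tables (planted
# curves, per-day indices, subject intercepts) make parameter-recovery
# scoring possible without re-deriving anything.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: 87 subjects, 14 days,
#' 4 prompts/day of 18 trials, mean daily bout counts of 28.4/34.7/6.9
#' (SED/LPA/MVPA), Pareto bout lengths with a 1-minute floor, prompt
#' compliance 0.75, and day-level outcome noise giving intraclass
#' correlations of about 0.70 (median RT) and 0.47 (correct trials). See the
#' package vignette for the rationale behind each default.
#'
#' @param n_subjects number of subjects
#' @param n_days protocol length in days; a warning is issued when not a
#'   multiple of 7 (day-of-week balance is then broken)
#' @param prompts_per_day EMA prompts per day
#' @param trials_per_session symbol-search trials per complete session
#' @param compliance probability a prompt is answered
#' @param wake_start,wake_end wake window clock hours
#' @param bout_count_means named per-class mean daily bout counts
#' @param bout_length_tail named per-class power-law tail exponents of the
#'   bout-length *density* (> 1; > 2 for a finite mean), scale fixed at the
#'   1-minute floor. This is the population analogue of the alpha index:
#'   lengths are sampled from a classic Pareto with survival exponent
#'   \code{tail - 1}, for which the alpha index consistently estimates
#'   \code{tail}
#' @param tail_sd subject-level log-normal SD applied to \code{tail - 1}
#'   (stable between-person differences in bout fragmentation); 0 disables
#' @param planted_beta_gini,planted_beta_alpha planted day-of-week effect
#'   curves: nested list \code{[[outcome]][[class]]} of length-7 numeric
#'   vectors (outcomes \code{"rt"}, \code{"accuracy"}); \code{NULL} plants
#'   zero everywhere
#' @param subject_sd,residual_sd named (\code{rt}, \code{accuracy})
#'   between-subject and day-level residual SDs on the outcome scales;
#'   the implied ICC is \code{subject_sd^2 / (subject_sd^2 + residual_sd^2)}
#' @param rt_baseline day-level median RT baseline (ms)
#' @param accuracy_baseline day-level correct-trials baseline
#' @param rt_sigma_log log-scale SD of trial RTs within a session
#' @param incomplete_rate probability an answered prompt is left incomplete
#' @param low_wear_rate probability a subject-day is generated with < 10 h of
#'   event coverage (deliberately injected invalid day)
#' @param x_min recordable bout floor (minutes)
#' @param max_bout_min cap on generated bout lengths (minutes)
#' @param start_date protocol start (a Sunday by default, so 14 days cover
#'   each day of week exactly twice)
#' @param seed default RNG seed used when the generator is called without one
#' @return validated list of class \code{"sim_config"}
#' @export
sim_config <- function(n_subjects = 87,
                       n_days = 14,
                       prompts_per_day = 4,
                       trials_per_session = 18,
                       compliance = 0.75,
                       wake_start = 6, wake_end = 22,
                       bout_count_means = c(SED = 28.4, LPA = 34.7, MVPA = 6.9),
                       bout_length_tail = c(SED = 2.5, LPA = 3.0, MVPA = 3.5),
                       tail_sd = 0.3,
                       planted_beta_gini = NULL,
                       planted_beta_alpha = NULL,
                       subject_sd = c(rt = 500, accuracy = 0.33),
                       residual_sd = c(rt = 330, accuracy = 0.35),
                       rt_baseline = 2327.9,
                       accuracy_baseline = 17.5,
                       rt_sigma_log = 0.35,
                       incomplete_rate = 0.02,
                       low_wear_rate = 0.035,
                       x_min = 1,
                       max_bout_min = 600,
                       start_date = as.Date("2024-01-07"),
                       seed = 1L) {
  cfg <- list(n_subjects = n_subjects, n_days = n_days,
              prompts_per_day = prompts_per_day,
              trials_per_session = trials_per_session,
              compliance = compliance,
              wake_start = wake_start, wake_end = wake_end,
              bout_count_means = bout_count_means,
              bout_length_tail = bout_length_tail,
              tail_sd = tail_sd,
              planted_beta_gini = normalize_planted(planted_beta_gini),
              planted_beta_alpha = normalize_planted(planted_beta_alpha),
              subject_sd = subject_sd, residual_sd = residual_sd,
              rt_baseline = rt_baseline, accuracy_baseline = accuracy_baseline,
              rt_sigma_log = rt_sigma_log,
              incomplete_rate = incomplete_rate,
              low_wear_rate = low_wear_rate,
              x_min = x_min, max_bout_min = max_bout_min,
              start_date = as.Date(start_date), seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

normalize_planted <- function(pb) {
  out <- list(rt = list(), accuracy = list())
  for (oc in c("rt", "accuracy"))
    for (k in BOUT_CLASSES)
      out[[oc]][[k]] <- rep(0, 7)
  if (is.null(pb)) return(out)
  for (oc in names(pb)) {
    if (!oc %in% c("rt", "accuracy"))
      stop_input("planted effects: unknown outcome '%s'", oc)
    for (k in names(pb[[oc]])) {
      if (!k %in% BOUT_CLASSES) stop_input("planted effects: unknown class '%s'", k)
      v <- pb[[oc]][[k]]
      if (length(v) != 7 || any(!is.finite(v)))
        stop_input("planted effects: %s/%s must be 7 finite values", oc, k)
      out[[oc]][[k]] <- as.numeric(v)
    }
  }
  out
}

validate_sim_config <- function(cfg) {
  stopifnot(is_count(cfg$n_subjects), cfg$n_subjects >= 1,
            is_count(cfg$n_days), cfg$n_days >= 1,
            is_count(cfg$prompts_per_day), is_count(cfg$trials_per_session))
  for (p in c("compliance", "incomplete_rate", "low_wear_rate"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop_input("sim_config: %s must be in [0, 1]", p)
  if (any(cfg$bout_length_tail <= 1))
    stop_input("sim_config: power-law tail exponents must be > 1")
  if (any(cfg$subject_sd < 0) || any(cfg$residual_sd < 0))
    stop_input("sim_config: SDs must be >= 0")
  if (cfg$wake_end <= cfg$wake_start) stop_input("sim_config: empty wake window")
  if (!setequal(names(cfg$bout_count_means), BOUT_CLASSES) ||
      !setequal(names(cfg$bout_length_tail), BOUT_CLASSES))
    stop_input("sim_config: bout_count_means / bout_length_tail need names SED, LPA, MVPA")
  if (cfg$n_days %% 7 != 0)
    warning("sim_config: n_days is not a multiple of 7; day-of-week cells will be unbalanced",
            call. = FALSE)
  invisible(cfg)
}

# Independent-oracle index formulas used for ground truth: the Gini here is
# the literal double loop, deliberately a different code path from
# gini_index()'s sorted form.
oracle_gini <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sum(abs(outer(x, x, "-"))) / (2 * n * sum(x))
}
oracle_alpha <- function(x, x_min = 1) {
  if (!length(x)) return(NA_real_)
  M <- sum(log(x / x_min)) / length(x)
  if (M <= 0) NA_real_ else 1 + 1 / M
}

draw_subjects <- function(cfg, seed) {
  set.seed(derive_seed(seed, 0L, 0L))
  n <- cfg$n_subjects
  age <- round(clamp(stats::rnorm(n, 68.5, 7.0), 60, 91), 1)
  sex <- stats::rbinom(n, 1, 0.379)
  edu <- sample(EDU_LEVELS, n, replace = TRUE, prob = c(0.195, 0.736, 0.069))
  b_rt <- stats::rnorm(n, 0, cfg$subject_sd[["rt"]])
  b_acc <- stats::rnorm(n, 0, cfg$subject_sd[["accuracy"]])
  # classic Pareto survival exponents: tail - 1, with subject heterogeneity
  shapes <- sapply(BOUT_CLASSES, function(k)
    (cfg$bout_length_tail[[k]] - 1) * exp(stats::rnorm(n, 0, cfg$tail_sd)))
  low_wear <- matrix(stats::runif(n * cfg$n_days) < cfg$low_wear_rate, n, cfg$n_days)
  list(demographics = data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                                 age = age, sex = sex, education = edu,
                                 stringsAsFactors = FALSE),
       b_rt = b_rt, b_acc = b_acc,
       shapes = matrix(shapes, n, 3, dimnames = list(NULL, BOUT_CLASSES)),
       low_wear = low_wear)
}

day_outcome_means <- function(cfg, dow, b_rt, b_acc, idx_alpha, idx_gini) {
  # idx_alpha / idx_gini: named per-class values for the day (NA -> no term)
  eff <- function(outcome) {
    tot <- 0
    for (k in BOUT_CLASSES) {
      g <- idx_gini[[k]]; a <- idx_alpha[[k]]
      if (is.finite(g)) tot <- tot + cfg$planted_beta_gini[[outcome]][[k]][dow] * g
      if (is.finite(a)) tot <- tot + cfg$planted_beta_alpha[[outcome]][[k]][dow] * a
    }
    tot
  }
  list(rt = cfg$rt_baseline + b_rt + eff("rt"),
       accuracy = clamp(cfg$accuracy_baseline + b_acc + eff("accuracy"),
                        0, cfg$trials_per_session))
}

#' Generate one subject-day of accelerometer events
#'
#' Draws per-class bout counts (Poisson around the configured means) and bout
#' lengths (Pareto with the subject's tail exponents, 1-minute scale), then
#' lays the bouts down in random order separated by \code{OTHER} standing
#' segments so that events exactly tile the wake window (or a shorter block
#' for an injected low-wear day). Each bout is emitted as 1-3 contiguous
#' events with MET values inside the class's defining interval.
#'
#' @param subject_id subject identifier
#' @param date calendar date of the simulated day
#' @param config a [sim_config()]
#' @param seed integer seed for this day's RNG stream (the cohort generator
#'   derives one per subject-day)
#' @param shapes named per-class classic Pareto survival exponents for this
#'   subject (the generator passes \code{tail - 1} plus subject noise)
#' @param low_wear inject a low-wear day (< 10 h of coverage)
#' @return list with \code{events} (tiling event table) and \code{bouts}
#'   (the generative bout list: \code{cls}, \code{length_min})
#' @export
generate_day_events <- function(subject_id, date, config, seed = NULL,
                                shapes = config$bout_length_tail - 1,
                                low_wear = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  wake_min <- (config$wake_end - config$wake_start) * 60
  cover_min <- if (low_wear) stats::runif(1, 7, 9.5) * 60 else wake_min

  counts <- stats::rpois(3, config$bout_count_means[BOUT_CLASSES])
  names(counts) <- BOUT_CLASSES
  cls <- rep(BOUT_CLASSES, counts)
  len <- numeric(length(cls))
  for (k in BOUT_CLASSES) {
    sel <- cls == k
    if (any(sel))
      len[sel] <- pmin(rpareto(sum(sel), shapes[[k]], config$x_min), config$max_bout_min)
  }
  ord <- sample.int(length(cls))
  cls <- cls[ord]; len <- len[ord]
  # keep bouts while they, plus minimal OTHER separators, fit the coverage
  budget <- 0.85 * cover_min
  keep <- cumsum(len + 0.25) <= budget
  cls <- cls[keep]; len <- len[keep]
  nb <- length(cls)

  remaining <- cover_min - sum(len)
  w <- stats::rexp(nb + 1)
  gaps <- 0.2 + (remaining - 0.2 * (nb + 1)) * w / sum(w)

  seg_cls <- character(2 * nb + 1)
  seg_len <- numeric(2 * nb + 1)
  seg_cls[seq(1, 2 * nb + 1, by = 2)] <- "OTHER"
  seg_len[seq(1, 2 * nb + 1, by = 2)] <- gaps
  if (nb) {
    seg_cls[seq(2, 2 * nb, by = 2)] <- cls
    seg_len[seq(2, 2 * nb, by = 2)] <- len
  }

  # split each segment into 1-3 contiguous events
  n_ev <- ifelse(seg_cls == "OTHER", 1L, sample(1:3, length(seg_cls), replace = TRUE))
  ev_cls <- rep(seg_cls, n_ev)
  ev_len <- numeric(sum(n_ev))
  pos <- 1L
  for (s in seq_along(seg_cls)) {
    k <- n_ev[s]
    if (k == 1L) frac <- 1 else {
      cuts <- sort(stats::runif(k - 1, 0.2, 0.8))
      frac <- diff(c(0, cuts, 1))
    }
    ev_len[pos:(pos + k - 1L)] <- seg_len[s] * frac
    pos <- pos + k
  }
  met <- numeric(length(ev_cls))
  posture <- character(length(ev_cls))
  for (k in c("OTHER", BOUT_CLASSES)) {
    sel <- ev_cls == k
    n_k <- sum(sel)
    if (!n_k) next
    met[sel] <- switch(k,
                       OTHER = stats::runif(n_k, 0.8, 1.24),
                       SED = stats::runif(n_k, 0.9, 1.24),
                       LPA = stats::runif(n_k, 1.25, 2.99),
                       MVPA = stats::runif(n_k, 3.0, 6.0))
    posture[sel] <- switch(k, OTHER = "standing", SED = "seated_reclined",
                           LPA = "stepping", MVPA = "stepping")
  }
  lead_min <- if (low_wear) stats::runif(1, 0, wake_min - cover_min) else 0
  day0 <- as.POSIXct(paste(as.Date(date), "00:00:00"), tz = "")
  t0 <- as.numeric(day0) + config$wake_start * 3600 + lead_min * 60
  starts <- t0 + cumsum(c(0, utils::head(ev_len, -1))) * 60
  events <- data.frame(subject_id = subject_id,
                       start = as.POSIXct(starts, origin = "1970-01-01", tz = ""),
                       duration_s = ev_len * 60,
                       posture = posture, met = met,
                       stringsAsFactors = FALSE)
  bouts <- data.frame(subject_id = subject_id, date = as.Date(date),
                      cls = cls, length_min = len, stringsAsFactors = FALSE)
  list(events = events, bouts = bouts)
}

#' Generate one EMA session of symbol-search trials
#'
#' Per-trial correctness is Bernoulli with success probability
#' \code{day_mean_correct / trials_per_session}; trial RTs are log-normal
#' with median \code{day_mean_rt} and log-SD \code{config$rt_sigma_log}
#' (so with zero RT noise the session median equals the day mean exactly).
#'
#' @param day_mean_rt day-level median RT (ms)
#' @param day_mean_correct day-level expected number of correct trials
#' @param config a [sim_config()]
#' @param n_trials number of trials to emit (defaults to a complete session)
#' @return data.frame with \code{trial_index}, \code{rt_ms}, \code{correct}
#' @export
generate_session_trials <- function(day_mean_rt, day_mean_correct, config,
                                    n_trials = config$trials_per_session) {
  stopifnot(is.finite(day_mean_rt), is.finite(day_mean_correct),
            day_mean_correct >= 0, day_mean_correct <= config$trials_per_session)
  p <- day_mean_correct / config$trials_per_session
  data.frame(trial_index = seq_len(n_trials),
             rt_ms = exp(log(day_mean_rt) + stats::rnorm(n_trials, 0, config$rt_sigma_log)),
             correct = stats::rbinom(n_trials, 1, p))
}

#' Generate a full synthetic cohort
#'
#' Event streams, EMA trials, demographics and truth tables for every
#' subject-day, with one RNG stream per subject split per day (regenerating a
#' subset of subjects reproduces their data exactly). Identical config and
#' seed give byte-identical tables.
#'
#' @param config a [sim_config()]
#' @param seed master seed (defaults to \code{config$seed})
#' @return list of class \code{"synthetic_cohort"}: \code{events},
#'   \code{trials}, \code{demographics}, and \code{truth} (planted curves,
#'   generative bout list, per-day true indices and outcome means, subject
#'   intercepts, low-wear flags)
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  subj <- draw_subjects(config, seed)
  n <- config$n_subjects
  ev_list <- list(); tr_list <- list(); bt_list <- list(); day_list <- list()
  for (i in seq_len(n)) {
    sid <- subj$demographics$subject_id[i]
    for (dday in seq_len(config$n_days)) {
      date <- config$start_date + (dday - 1)
      dw <- dow_of(date)
      day <- generate_day_events(sid, date, config,
                                 seed = derive_seed(seed, i, dday),
                                 shapes = subj$shapes[i, ],
                                 low_wear = subj$low_wear[i, dday])
      idx_a <- idx_g <- nb <- stats::setNames(rep(NA_real_, 3), BOUT_CLASSES)
      for (k in BOUT_CLASSES) {
        x <- day$bouts$length_min[day$bouts$cls == k]
        nb[[k]] <- length(x)
        idx_a[[k]] <- oracle_alpha(x, config$x_min)
        idx_g[[k]] <- oracle_gini(x)
      }
      mu <- day_outcome_means(config, dw, subj$b_rt[i], subj$b_acc[i], idx_a, idx_g)
      day_rt <- mu$rt + stats::rnorm(1, 0, config$residual_sd[["rt"]])
      day_rt <- max(day_rt, 200)
      day_acc <- clamp(mu$accuracy + stats::rnorm(1, 0, config$residual_sd[["accuracy"]]),
                       0, config$trials_per_session)

      wake_h <- config$wake_end - config$wake_start
      anchors <- config$wake_start + 1 + (seq_len(config$prompts_per_day) - 1) *
        (wake_h - 2) / config$prompts_per_day
      prompt_h <- clamp(anchors + stats::runif(config$prompts_per_day, -0.5, 0.5),
                        config$wake_start, config$wake_end - 0.1)
      answered <- stats::runif(config$prompts_per_day) < config$compliance
      for (s in which(answered)) {
        n_tr <- if (stats::runif(1) < config$incomplete_rate)
          sample(5:(config$trials_per_session - 1), 1) else config$trials_per_session
        tr <- generate_session_trials(day_rt, day_acc, config, n_tr)
        tr <- cbind(subject_id = sid,
                    session_start = format(as.POSIXct(paste(date, "00:00:00"), tz = "") +
                                             prompt_h[s] * 3600, "%Y-%m-%d %H:%M:%S"),
                    tr, stringsAsFactors = FALSE)
        tr_list[[length(tr_list) + 1L]] <- tr
      }
      ev_list[[length(ev_list) + 1L]] <- day$events
      bt_list[[length(bt_list) + 1L]] <- day$bouts
      day_list[[length(day_list) + 1L]] <-
        data.frame(subject_id = sid, date = as.Date(date), dow = dw,
                   low_wear = subj$low_wear[i, dday],
                   n_answered = sum(answered),
                   true_rt = day_rt, true_accuracy = day_acc,
                   alpha_SED = idx_a[["SED"]], gini_SED = idx_g[["SED"]], n_SED = nb[["SED"]],
                   alpha_LPA = idx_a[["LPA"]], gini_LPA = idx_g[["LPA"]], n_LPA = nb[["LPA"]],
                   alpha_MVPA = idx_a[["MVPA"]], gini_MVPA = idx_g[["MVPA"]], n_MVPA = nb[["MVPA"]],
                   stringsAsFactors = FALSE)
    }
  }
  events <- do.call(rbind, ev_list)
  events$start <- format(events$start, "%Y-%m-%d %H:%M:%OS3")
  trials <- if (length(tr_list)) do.call(rbind, tr_list) else
    data.frame(subject_id = character(), session_start = character(),
               trial_index = integer(), rt_ms = numeric(), correct = integer())
  structure(list(events = events, trials = trials,
                 demographics = subj$demographics,
                 truth = list(planted_beta_gini = config$planted_beta_gini,
                              planted_beta_alpha = config$planted_beta_alpha,
                              bouts = do.call(rbind, bt_list),
                              days = do.call(rbind, day_list),
                              subject_intercepts = data.frame(
                                subject_id = subj$demographics$subject_id,
                                b_rt = subj$b_rt, b_accuracy = subj$b_acc),
                              tail_shapes = subj$shapes),
                 config = config, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x %d days; %d events, %d trials\n",
              x$config$n_subjects, x$config$n_days, nrow(x$events), nrow(x$trials)))
  invisible(x)
}

#' True per-day distribution indices from the generator's bout list
#'
#' Recomputes alpha/Gini/bout counts per (subject, date, class) from the
#' cohort's own generative bout list, using the literal double-loop Gini and
#' direct alpha formulas — an independent code path from
#' [gini_index()]/[alpha_index()], so agreement between the two is a real
#' cross-check.
#'
#' @param cohort a \code{"synthetic_cohort"}, or a bout data.frame with
#'   columns \code{subject_id, date, cls, length_min}
#' @param x_min recordable floor (minutes)
#' @return data.frame: \code{subject_id, date, cls, alpha, gini, n_bouts}
#' @export
true_indices <- function(cohort, x_min = 1) {
  bouts <- if (inherits(cohort, "synthetic_cohort")) cohort$truth$bouts else cohort
  bt <- data.table::as.data.table(bouts)
  grid <- bt[, .(date = unique(date)), by = subject_id]
  grid <- grid[, .(cls = BOUT_CLASSES), by = .(subject_id, date)]
  ix <- bt[, .(alpha = oracle_alpha(length_min, x_min),
               gini = oracle_gini(length_min),
               n_bouts = .N),
           by = .(subject_id, date, cls)]
  out <- ix[grid, on = c("subject_id", "date", "cls")]
  out[is.na(n_bouts), n_bouts := 0L]
  data.table::setorder(out, subject_id, date, cls)
  as.data.frame(out)
}

#' Write a synthetic cohort to CSV + JSON
#'
#' Events, trials and demographics in the dialects the readers expect, plus a
#' truth JSON with the planted curves and per-day true indices.
#'
#' @param cohort a \code{"synthetic_cohort"}
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of written paths
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("events.csv", "trials.csv", "demographics.csv", "truth.json"))
  data.table::fwrite(cohort$events, paths[1])
  data.table::fwrite(cohort$trials, paths[2])
  data.table::fwrite(cohort$demographics, paths[3])
  truth <- cohort$truth
  truth$days$date <- as.character(truth$days$date)
  truth$bouts <- NULL   # bulky; per-day indices in `days` are the scoring hook
  jsonlite::write_json(truth, paths[4], auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}

# ---- fast day-level path ---------------------------------------------------

#' Day-level synthetic cohort (vectorized path for simulation studies)
#'
#' Generates the same day-level statistical structure as [generate_cohort()]
#' — Poisson bout counts, Pareto bout lengths, realized per-day indices,
#' planted day-of-week effects, subject intercepts — but skips the
#' event-stream and trial-stream plumbing (all days complete and valid), and
#' returns the day-of-week-matched analysis table directly. Used by the
#' Monte-Carlo calibration and recovery studies, where thousands of cohorts
#' are needed; it has its own RNG stream layout, so it is deterministic in
#' (config, seed) but not stream-identical to the event-level path.
#'
#' @param config a [sim_config()]
#' @param seed master seed
#' @param dow_aggregation how the day-of-week regressors are formed:
#'   \code{"pool"} (default, pool bout lengths across the dow's dates before
#'   indexing) or \code{"per_day_mean"} (average the per-date indices). The
#'   planted outcome model acts on per-date indices, so \code{"per_day_mean"}
#'   makes the regressor coincide exactly with the generative quantity;
#'   under \code{"pool"} the estimand is shifted by the pooled-vs-averaged
#'   index discrepancy (see the vignette)
#' @return list: \code{observations} (analysis table, one row per subject x
#'   dow), \code{day_table} (per-day outcomes and true indices),
#'   \code{demographics}, \code{truth}
#' @export
cohort_table <- function(config, seed = config$seed,
                         dow_aggregation = c("pool", "per_day_mean")) {
  dow_aggregation <- match.arg(dow_aggregation)
  stopifnot(inherits(config, "sim_config"))
  subj <- draw_subjects(config, seed)
  set.seed(derive_seed(seed, 1L, 999983L))
  n <- config$n_subjects
  nd <- config$n_days
  day <- data.table::CJ(si = seq_len(n), dday = seq_len(nd), sorted = TRUE)
  day[, date := config$start_date + dday - 1]
  day[, dow := dow_of(date)]
  day[, day_id := .I]

  idx_list <- vector("list", 3)
  len_store <- vector("list", 3)
  for (kk in seq_along(BOUT_CLASSES)) {
    k <- BOUT_CLASSES[kk]
    cnt <- stats::rpois(nrow(day), config$bout_count_means[[k]])
    shp <- subj$shapes[day$si, k]
    lens <- pmin(rpareto(sum(cnt), rep(shp, cnt), config$x_min), config$max_bout_min)
    dt <- data.table::data.table(day_id = rep(day$day_id, cnt), x = lens)
    dt[, lx := log(x / config$x_min)]
    data.table::setorder(dt, day_id, x)
    dt[, r := data.table::rowid(day_id)]
    # sorted-rank Gini: G = 2 sum(r x)/(n sum x) - (n+1)/n; GForce-friendly
    ix <- dt[, .(sx = sum(x), srx = sum(r * x), M = mean(lx), n_bouts = .N), by = day_id]
    ix[, alpha := data.table::fifelse(M > 0, 1 + 1 / M, NA_real_)]
    ix[, gini := 2 * srx / (n_bouts * sx) - (n_bouts + 1) / n_bouts]
    full <- ix[data.table::data.table(day_id = day$day_id), on = "day_id"]
    full[is.na(n_bouts), n_bouts := 0L]
    idx_list[[kk]] <- full
    dt[, si := day$si[day_id]]
    dt[, dow := day$dow[day_id]]
    len_store[[kk]] <- dt
  }

  eff_rt <- eff_acc <- rep(0, nrow(day))
  for (kk in seq_along(BOUT_CLASSES)) {
    k <- BOUT_CLASSES[kk]
    g <- idx_list[[kk]]$gini; a <- idx_list[[kk]]$alpha
    bg_rt <- config$planted_beta_gini$rt[[k]][day$dow]
    ba_rt <- config$planted_beta_alpha$rt[[k]][day$dow]
    bg_ac <- config$planted_beta_gini$accuracy[[k]][day$dow]
    ba_ac <- config$planted_beta_alpha$accuracy[[k]][day$dow]
    eff_rt <- eff_rt + ifelse(is.finite(g), bg_rt * g, 0) + ifelse(is.finite(a), ba_rt * a, 0)
    eff_acc <- eff_acc + ifelse(is.finite(g), bg_ac * g, 0) + ifelse(is.finite(a), ba_ac * a, 0)
  }
  day[, rt := pmax(config$rt_baseline + subj$b_rt[si] + eff_rt +
                     stats::rnorm(.N, 0, config$residual_sd[["rt"]]), 200)]
  day[, accuracy := clamp(config$accuracy_baseline + subj$b_acc[si] + eff_acc +
                            stats::rnorm(.N, 0, config$residual_sd[["accuracy"]]),
                          0, config$trials_per_session)]

  ydow <- day[, .(median_rt = mean(rt), mean_correct = mean(accuracy), n_days = .N),
              by = .(si, dow)]
  wide_parts <- list()
  for (kk in seq_along(BOUT_CLASSES)) {
    k <- BOUT_CLASSES[kk]
    if (dow_aggregation == "pool") {
      dt <- len_store[[kk]]
      data.table::setorder(dt, si, dow, x)
      dt[, rp := data.table::rowid(si, dow)]
      pool <- dt[, .(sx = sum(x), srx = sum(rp * x), M = mean(lx), n_bouts = .N),
                 by = .(si, dow)]
      pool[, alpha := data.table::fifelse(M > 0, 1 + 1 / M, NA_real_)]
      pool[, gini := 2 * srx / (n_bouts * sx) - (n_bouts + 1) / n_bouts]
      pool <- pool[, .(si, dow, alpha, gini, n_bouts)]
    } else {
      perday <- data.table::data.table(si = day$si, dow = day$dow,
                                       alpha = idx_list[[kk]]$alpha,
                                       gini = idx_list[[kk]]$gini,
                                       n = idx_list[[kk]]$n_bouts)
      pool <- perday[, .(alpha = if (all(is.na(alpha))) NA_real_ else mean(alpha, na.rm = TRUE),
                         gini = if (all(is.na(gini))) NA_real_ else mean(gini, na.rm = TRUE),
                         n_bouts = sum(n)), by = .(si, dow)]
    }
    cnts <- idx_list[[kk]]
    cnts <- data.table::data.table(si = day$si, dow = day$dow, n = cnts$n_bouts)
    nb <- cnts[, .(nbouts = mean(n)), by = .(si, dow)]
    m <- pool[nb, on = c("si", "dow")]
    m[is.na(alpha) & is.na(gini) & is.na(n_bouts), n_bouts := 0L]
    data.table::setnames(m, c("alpha", "gini", "nbouts"),
                         paste0(c("alpha_", "gini_", "nbouts_"), k))
    wide_parts[[kk]] <- m[, c("si", "dow", paste0(c("alpha_", "gini_", "nbouts_"), k)), with = FALSE]
  }
  obs <- Reduce(function(a, b) a[b, on = c("si", "dow")], wide_parts, accumulate = FALSE)
  obs <- obs[ydow, on = c("si", "dow")]
  dem <- data.table::as.data.table(subj$demographics)
  dem[, si := .I]
  dem[, `:=`(edu_college = as.integer(education == "college"),
             edu_advanced = as.integer(education == "advanced"))]
  obs <- dem[, .(si, subject_id, age, sex, edu_college, edu_advanced)][obs, on = "si"]
  obs[, si := NULL]
  data.table::setcolorder(obs, c("subject_id", "dow", "median_rt", "mean_correct", "n_days"))
  data.table::setorder(obs, subject_id, dow)

  day_out <- day[, .(subject_id = subj$demographics$subject_id[si], date, dow,
                     rt, accuracy)]
  for (kk in seq_along(BOUT_CLASSES)) {
    k <- BOUT_CLASSES[kk]
    day_out[, paste0(c("alpha_", "gini_", "n_"), k) :=
              idx_list[[kk]][, .(alpha, gini, n_bouts)]]
  }
  list(observations = as.data.frame(obs),
       day_table = as.data.frame(day_out),
       demographics = subj$demographics,
       truth = list(planted_beta_gini = config$planted_beta_gini,
                    planted_beta_alpha = config$planted_beta_alpha,
                    subject_intercepts = data.frame(
                      subject_id = subj$demographics$subject_id,
                      b_rt = subj$b_rt, b_accuracy = subj$b_acc)))
}

#' Smooth weekday-effect curve with a quiet Sunday
#'
#' Builds a planted effect curve that is exactly zero on Sunday (d = 1) and
#' as close to a constant \code{effect} as the basis allows across Monday to
#' Friday (Saturday targeted at half strength), constructed inside the span
#' of the default K = 5 cyclic basis so that the fitted model can represent
#' the truth without approximation bias. The Sunday zero is imposed as a
#' hard constraint and the weekday targets by least squares, which keeps the
#' weekday values near \code{effect} without the oscillation exact
#' interpolation would force. Used by the qualitative-pattern recovery
#' studies.
#'
#' @param effect weekday effect size (sign included)
#' @param K basis dimension the curve should live in (default 5)
#' @return length-7 numeric curve over d = 1..7
#' @export
weekday_effect_curve <- function(effect, K = 5) {
  B <- cyclic_basis(1:7, K)
  target <- c(0, rep(effect, 5), effect / 2)
  # minimize ||B theta - target||^2 subject to B[1, ] theta = 0
  a <- B[1, , drop = FALSE]
  Q <- qr.Q(qr(t(a)), complete = TRUE)[, -1, drop = FALSE]  # null space of the constraint
  BQ <- B %*% Q
  th <- Q %*% qr.solve(BQ, target)
  drop(B %*% th)
}
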