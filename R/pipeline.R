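# End-to-end orchestration: simulate (or load) -> extract bouts -> cognition
# -> indices -> QC/alignment -> six varying-coefficient fits (2 outcomes x
# 3 bout classes) -> optional power study, with a manifest recording row
# counts, exclusions and fit summaries at every stage.

#' Default pipeline configuration
#'
#' @param out_dir output directory
#' @param seed master seed
#' @param simulate list of [sim_config()] overrides (a simulate-block); set
#'   to \code{NULL} and provide \code{paths} to run on existing CSVs
#' @param paths named list (\code{events}, \code{trials},
#'   \code{demographics}) of input CSVs when not simulating
#' @param wear_hours_min,sessions_min valid-day thresholds
#' @param wake_window wake window clock hours
#' @param dow_aggregation \code{"pool"} or \code{"per_day_mean"}
#' @param rt_mode day-level RT aggregation, see [aggregate_day()]
#' @param K,smoothing model settings shared by the six fits
#' @param power optional [power_config()] overrides list; \code{NULL} skips
#'   the power stage
#' @return list of class \code{"pipeline_config"}
#' @export
pipeline_config <- function(out_dir = tempfile("boutcog_run_"),
                            seed = 1L,
                            simulate = list(),
                            paths = NULL,
                            wear_hours_min = 10,
                            sessions_min = 1,
                            wake_window = c(6, 22),
                            dow_aggregation = "pool",
                            rt_mode = "pooled",
                            K = 5,
                            smoothing = "REML",
                            power = NULL) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
              paths = paths, wear_hours_min = wear_hours_min,
              sessions_min = sessions_min, wake_window = wake_window,
              dow_aggregation = dow_aggregation, rt_mode = rt_mode,
              K = K, smoothing = smoothing, power = power)
  rep <- validate_config(cfg)
  if (length(rep$errors))
    stop_input("pipeline_config: %s", paste(rep$errors, collapse = "; "))
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Schema check with precise error paths; unknown keys produce warnings, not
#' errors, so configs stay forward compatible. Nothing is run when the error
#' list is non-empty.
#'
#' @param config a list or \code{"pipeline_config"} (or a YAML file path)
#' @return list with character vectors \code{errors} and \code{warnings}
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  known <- c("out_dir", "seed", "simulate", "paths", "wear_hours_min",
             "sessions_min", "wake_window", "dow_aggregation", "rt_mode",
             "K", "smoothing", "power")
  errors <- character(); warnings <- character()
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    warnings <- c(warnings, sprintf("unknown key(s): %s", paste(unknown, collapse = ", ")))
  need_num <- function(key, lo = -Inf) {
    v <- config[[key]]
    if (is.null(v)) errors <<- c(errors, sprintf("missing key: %s", key))
    else if (!is.numeric(v) || any(!is.finite(v)) || any(v < lo))
      errors <<- c(errors, sprintf("invalid value for %s", key))
  }
  need_num("wear_hours_min", lo = 0)
  need_num("sessions_min", lo = 0)
  need_num("seed")
  if (!is.null(config$wear_hours_min) && is.numeric(config$wear_hours_min) &&
      all(is.finite(config$wear_hours_min)) && any(config$wear_hours_min <= 0))
    errors <- c(errors, "wear_hours_min must be positive")
  if (!is.null(config$dow_aggregation) &&
      !config$dow_aggregation %in% c("pool", "per_day_mean"))
    errors <- c(errors, "dow_aggregation must be 'pool' or 'per_day_mean'")
  if (!is.null(config$rt_mode) && !config$rt_mode %in% c("pooled", "session_median"))
    errors <- c(errors, "rt_mode must be 'pooled' or 'session_median'")
  if (is.null(config$simulate) && is.null(config$paths))
    errors <- c(errors, "need either a simulate block or input paths")
  if (!is.null(config$paths)) {
    miss <- setdiff(c("events", "trials", "demographics"), names(config$paths))
    if (length(miss))
      errors <- c(errors, sprintf("paths: missing %s", paste(miss, collapse = ", ")))
  }
  list(errors = errors, warnings = warnings)
}

#' Run the full analysis pipeline
#'
#' simulate/load -> bout extraction -> cognition aggregation -> day-of-week
#' indices -> valid-day QC and alignment -> six varying-coefficient fits
#' (median RT and correct trials, each against SED/LPA/MVPA indices) ->
#' optional power study. All stage outputs are written to
#' \code{config$out_dir}; the returned manifest (also written as JSON)
#' records the seed, config hash, per-stage row counts, exclusion
#' percentages and one summary line per fit.
#'
#' @param config a [pipeline_config()] (or a YAML file path / plain list)
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, config)
  }
  rep <- validate_config(config)
  for (w in rep$warnings) warning(w, call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }

  if (!is.null(config$simulate)) {
    sim_cfg <- stage("simulate", do.call(sim_config, config$simulate))
    cohort <- stage("simulate", generate_cohort(sim_cfg, seed = config$seed))
    stage("simulate", write_cohort(cohort, config$out_dir))
    events <- cohort$events
    trials <- cohort$trials
    demographics <- cohort$demographics
  } else {
    events <- stage("load", read_events(config$paths$events,
                                        format = config$paths$format %||% "native"))
    trials <- stage("load", read_trials(config$paths$trials))
    demographics <- stage("load", utils::read.csv(config$paths$demographics,
                                                  stringsAsFactors = FALSE))
  }

  ex <- stage("extract", summarize_days(events, wake_window = config$wake_window))
  data.table::fwrite(ex$bouts, file.path(config$out_dir, "bouts.csv"))
  data.table::fwrite(ex$day_summary, file.path(config$out_dir, "day_summary.csv"))

  cogdays <- stage("cognition", cognitive_days(trials, rt_mode = config$rt_mode))
  data.table::fwrite(cogdays, file.path(config$out_dir, "cogdays.csv"))

  valid <- stage("align", flag_valid_days(ex$day_summary, cogdays,
                                          wear_hours_min = config$wear_hours_min,
                                          sessions_min = config$sessions_min))
  data.table::fwrite(valid, file.path(config$out_dir, "valid_days.csv"))
  excl <- exclusion_report(valid)
  jsonlite::write_json(excl, file.path(config$out_dir, "exclusion_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  ix <- stage("indices", dow_indices(ex$bouts,
                                     valid[valid$valid, c("subject_id", "date")],
                                     aggregation = config$dow_aggregation))
  index_report(ix, file.path(config$out_dir, "indices.csv"))

  tab <- stage("align", build_analysis_table(valid, cogdays, ix, demographics))
  data.table::fwrite(tab, file.path(config$out_dir, "analysis_table.csv"), na = "NA")

  fits <- list()
  fit_summaries <- list()
  for (oc in c("median_rt", "mean_correct")) {
    for (k in BOUT_CLASSES) {
      key <- paste(oc, k, sep = "_")
      spec <- model_spec(outcome = oc, bout_class = k, K = config$K,
                         smoothing = config$smoothing)
      fit <- stage(paste0("fit:", key), fit_model(tab, spec))
      fits[[key]] <- fit
      curves <- fit$curves
      data.table::fwrite(curves, file.path(config$out_dir, sprintf("curves_%s.csv", key)))
      res <- list(outcome = oc, bout_class = k,
                  n_obs = fit$n_obs, n_subjects = fit$n_subjects,
                  n_dropped = fit$n_dropped,
                  adj_r2 = fit$adj_r2, sigma2 = fit$sigma2, sigma2_b = fit$sigma2_b,
                  wald = fit$wald, curves = curves,
                  mean_abs_effect = stats::setNames(
                    lapply(unique(curves$term), function(tm) mean_abs_effect(fit, tm)),
                    unique(curves$term)))
      jsonlite::write_json(res, file.path(config$out_dir, sprintf("fit_%s.json", key)),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
      gini_term <- paste0("gini_", k)
      fit_summaries[[key]] <- list(
        outcome = oc, bout_class = k, n_obs = fit$n_obs,
        adj_r2 = fit$adj_r2,
        gini_wald_p = fit$wald$p[fit$wald$term == gini_term],
        gini_mean_abs_effect = mean_abs_effect(fit, gini_term))
    }
  }

  power_res <- NULL
  if (!is.null(config$power)) {
    pc <- do.call(power_config, utils::modifyList(list(seed = config$seed),
                                                  config$power))
    power_res <- stage("power", simulate_power(pc))
    data.table::fwrite(power_res$cells, file.path(config$out_dir, "power.csv"))
    jsonlite::write_json(power_table(power_res, digits = NULL),
                         file.path(config$out_dir, "power_table.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  cfg_path <- file.path(config$out_dir, "config.json")
  cfg_serializable <- unclass(config)
  cfg_serializable$out_dir <- NULL
  jsonlite::write_json(cfg_serializable, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  manifest <- list(
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    rows = list(events = nrow(events), trials = nrow(trials),
                bouts = nrow(ex$bouts), day_summary = nrow(ex$day_summary),
                cogdays = nrow(cogdays), valid_days = nrow(valid),
                indices = nrow(ix), analysis_table = nrow(tab)),
    exclusions = excl[c("n_person_days", "n_excluded", "pct_excluded")],
    fits = fit_summaries,
    power = if (!is.null(power_res)) power_res$cells else NULL)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  manifest$fit_objects <- fits
  invisible(manifest)
}
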