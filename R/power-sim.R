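# Monte-Carlo power study for the multilevel daily-diary design: days nested
# in subjects, a constant standardized effect beta of a day-level index, and
# a random-intercept mixed model as the fitted test.

#' Power simulation configuration
#'
#' Outcomes are standardized to unit total variance, so \code{beta_grid} is
#' on a standardized scale; \code{icc_grid} sets the share of outcome
#' variance carried by stable between-subject differences. The default grid
#' spans the intraclass correlations typical of day-level ambulatory
#' processing-speed (high, ~0.7) and accuracy (moderate, ~0.45) outcomes.
#'
#' @param n_subjects number of subjects (default 87)
#' @param days_per_subject days per subject (default 14)
#' @param icc_grid intraclass correlations in (0, 1) to simulate (0 allowed:
#'   no subject effect)
#' @param beta_grid standardized effect sizes (default 0, 0.05, 0.07, 0.10)
#' @param n_sims simulations per (icc, beta) cell (>= 100 for reported cells)
#' @param alpha_level test level (default 0.05)
#' @param seed RNG seed
#' @return list of class \code{"power_config"}
#' @export
power_config <- function(n_subjects = 87, days_per_subject = 14,
                         icc_grid = c(0.45, 0.70),
                         beta_grid = c(0, 0.05, 0.07, 0.10),
                         n_sims = 500, alpha_level = 0.05, seed = 1L) {
  stopifnot(is_count(n_subjects), is_count(days_per_subject),
            length(icc_grid) >= 1, all(icc_grid >= 0), all(icc_grid < 1),
            length(beta_grid) >= 1, n_sims >= 1,
            alpha_level > 0, alpha_level < 1)
  if (n_sims < 100)
    warning("power_config: n_sims < 100; cells are too noisy to report", call. = FALSE)
  structure(list(n_subjects = n_subjects, days_per_subject = days_per_subject,
                 icc_grid = icc_grid, beta_grid = beta_grid, n_sims = n_sims,
                 alpha_level = alpha_level, seed = as.integer(seed)),
            class = "power_config")
}

#' Run the Monte-Carlo power simulation
#'
#' For each (icc, beta) cell, simulates
#' \eqn{y_{ij} = b_i + \beta x_{ij} + e_{ij}} with
#' \eqn{Var(b) = icc}, \eqn{Var(e) = 1 - icc} and day-level
#' \eqn{x_{ij} \sim N(0, 1)}, fits the random-intercept model with
#' \code{lme4::lmer} (REML), and rejects when the Wald p-value of the
#' \eqn{\beta} estimate is below \code{alpha_level}. Boundary (singular)
#' fits — common when the true ICC is near zero — are counted and reported
#' but kept in the denominator, since the Wald test of a fixed effect remains
#' well defined at the variance boundary.
#'
#' @param config a [power_config()]
#' @return object of class \code{"power_result"}: data.frame \code{cells}
#'   with columns \code{icc, beta, power, mcse, n_sims, n_singular}, plus the
#'   config and seed
#' @export
simulate_power <- function(config) {
  stopifnot(inherits(config, "power_config"))
  ns <- config$n_subjects; nd <- config$days_per_subject
  N <- ns * nd
  id <- factor(rep(seq_len(ns), each = nd))
  grid <- expand.grid(icc = config$icc_grid, beta = config$beta_grid,
                      KEEP.OUT.ATTRS = FALSE)
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    icc <- grid$icc[g]; beta <- grid$beta[g]
    set.seed(derive_seed(config$seed, g, 271L))
    rej <- 0L; singular <- 0L
    for (s in seq_len(config$n_sims)) {
      x <- stats::rnorm(N)
      b <- stats::rnorm(ns, 0, sqrt(icc))
      y <- b[as.integer(id)] + beta * x + stats::rnorm(N, 0, sqrt(1 - icc))
      fit <- suppressMessages(lme4::lmer(y ~ x + (1 | id), REML = TRUE, control = ctrl))
      if (lme4::isSingular(fit, tol = 1e-4)) singular <- singular + 1L
      cf <- lme4::fixef(fit)[["x"]]
      se <- sqrt(stats::vcov(fit)["x", "x"])
      p <- 2 * stats::pnorm(-abs(cf / se))
      if (p < config$alpha_level) rej <- rej + 1L
    }
    pow <- rej / config$n_sims
    rows[[g]] <- data.frame(icc = icc, beta = beta, power = pow,
                            mcse = sqrt(pow * (1 - pow) / config$n_sims),
                            n_sims = config$n_sims, n_singular = singular)
  }
  structure(list(cells = do.call(rbind, rows), config = config,
                 seed = config$seed),
            class = "power_result")
}

#' Power table (rows = ICC, columns = beta)
#'
#' Formats a [simulate_power()] result in the conventional reporting shape:
#' one row per intraclass correlation, one column per standardized effect
#' size, cells holding the estimated power.
#'
#' @param result a \code{"power_result"}
#' @param digits rounding for display (default 3); \code{NULL} keeps full
#'   precision
#' @return data.frame with an \code{icc} column and one \code{beta_*} column
#'   per effect size
#' @export
power_table <- function(result, digits = 3) {
  stopifnot(inherits(result, "power_result"))
  cells <- data.table::as.data.table(result$cells)
  wide <- data.table::dcast(cells, icc ~ beta, value.var = "power")
  data.table::setnames(wide, setdiff(names(wide), "icc"),
                       paste0("beta_", setdiff(names(wide), "icc")))
  out <- as.data.frame(wide)
  if (!is.null(digits)) out[-1] <- lapply(out[-1], round, digits = digits)
  out
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo power: %d subjects x %d days, %d sims/cell, level %.3g\n",
              x$config$n_subjects, x$config$days_per_subject,
              x$config$n_sims, x$config$alpha_level))
  print(power_table(x), row.names = FALSE)
  if (any(x$cells$n_singular > 0))
    cat(sprintf("  (%d boundary fits across all cells, kept in denominators)\n",
                sum(x$cells$n_singular)))
  invisible(x)
}
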