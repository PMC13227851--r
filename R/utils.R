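# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw Pareto-distributed bout lengths
#'
#' Inverse-CDF sampler for the Pareto distribution with density
#' \eqn{f(x) = a x_m^a / x^{a+1}} for \eqn{x \ge x_m}. Used by the synthetic
#' cohort generator; the scale \code{x_min} is the 1-minute recordable floor,
#' so the population power-law exponent equals \code{shape}.
#'
#' @param n number of draws
#' @param shape tail exponent (> 0; heavy-tailed for shape near 1)
#' @param x_min scale (minimum value), default 1
#' @return numeric vector of length \code{n}
#' @export
rpareto <- function(n, shape, x_min = 1) {
  stopifnot(shape > 0, x_min > 0)
  x_min * stats::runif(n)^(-1 / shape)
}

# Deterministic sub-seed for (subject, day) RNG streams. Keeps everything
# below 2^31 - 1 so set.seed() accepts it on 32-bit integer platforms.
derive_seed <- function(master, i, j = 0L) {
  m <- as.double(master) %% 100000
  as.integer(((m * 20011 + as.double(i) * 7919 + as.double(j) * 104729) %% 2147483629) + 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Day-of-week code used throughout: 1 = Sunday ... 7 = Saturday.
dow_of <- function(date) {
  as.POSIXlt(as.Date(date))$wday + 1L
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
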