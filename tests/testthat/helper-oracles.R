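# Independent oracles and fixture builders used across the suite.

# literal double-loop Gini: the printed definition, O(n^2)
gini_loop <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sum(abs(outer(x, x, "-"))) / (2 * n * sum(x))
}

# direct alpha evaluation
alpha_direct <- function(x, x_min = 1) {
  M <- mean(log(x / x_min))
  if (M <= 0) NA_real_ else 1 + 1 / M
}

# interval-union length (hours) clipped to a window, by sort-and-merge
union_hours <- function(starts, ends, w0, w1) {
  s <- pmax(starts, w0); e <- pmin(ends, w1)
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  if (!length(s)) return(0)
  o <- order(s); s <- s[o]; e <- e[o]
  tot <- 0; cs <- s[1]; ce <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > ce) { tot <- tot + (ce - cs); cs <- s[i]; ce <- e[i] }
    else ce <- max(ce, e[i])
  }
  (tot + (ce - cs)) / 3600
}

# build a toy event stream: consecutive events starting at `origin`,
# with per-event duration (s), met and posture
mk_events <- function(durations_s, met, posture,
                      subject_id = "T01",
                      origin = as.POSIXct("2024-01-08 06:00:00", tz = ""),
                      gaps_s = 0) {
  gaps_s <- rep(gaps_s, length.out = length(durations_s))
  starts <- origin + cumsum(c(0, head(durations_s + gaps_s, -1)))
  data.frame(subject_id = subject_id, start = starts,
             duration_s = durations_s, posture = posture, met = met,
             stringsAsFactors = FALSE)
}

# power-law bout-length sampler parameterized by the density exponent
# (the population value of the alpha index); classic Pareto survival
# exponent is tail - 1
rpowerlaw <- function(n, tail, x_min = 1) {
  x_min * runif(n)^(-1 / (tail - 1))
}

# quick trial-table builder: one session of n trials
mk_session <- function(rt, correct, subject_id = "T01",
                       session_start = "2024-01-08 09:00:00") {
  data.frame(subject_id = subject_id, session_start = session_start,
             trial_index = seq_along(rt), rt_ms = rt,
             correct = as.integer(correct), stringsAsFactors = FALSE)
}
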