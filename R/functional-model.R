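# Day-of-week varying-coefficient regression.
#
# Each (subject i, day-of-week d) analysis row contributes
#   Y_i(d) = beta_0(d) + alpha_i(d) beta_1(d) + G_i(d) beta_2(d) + N_i(d) beta_3(d)
#            + Age_i beta_4(d) + Sex_i beta_5(d) + Edu_i beta_6(d) + b_i + e_i(d)
# with every coefficient curve beta_j(d) expanded in a cyclic spline basis on
# the weekly circle, a circulant difference penalty per curve, and a scalar
# subject random intercept b_i absorbing within-subject correlation across the
# week. Smoothing parameters and the intercept variance are estimated by REML
# in the usual penalized-regression-as-mixed-model formulation; pointwise
# intervals use the Bayesian posterior covariance of the spline coefficients.

#' Model specification for the day-of-week varying-coefficient regression
#'
#' @param outcome which day-level cognitive outcome to model:
#'   \code{"median_rt"} (ms) or \code{"mean_correct"} (trials)
#' @param bout_class which activity class supplies the alpha/Gini/bout-count
#'   predictors: \code{"SED"}, \code{"LPA"} or \code{"MVPA"}
#' @param K cyclic basis dimension per coefficient curve (3..7; default 5).
#'   \code{K = 7} with \code{smoothing = "fixed"}, \code{lambda = 0} is the
#'   saturated, unpenalized parameterization
#' @param penalty_order difference order of the circulant penalty
#' @param smoothing \code{"REML"} (default) or \code{"fixed"} (use
#'   \code{lambda} as given)
#' @param lambda optional fixed smoothing parameters: scalar or one value per
#'   coefficient curve (recycled); only used when \code{smoothing = "fixed"}
#' @param random_intercept include the scalar subject random intercept
#'   (default \code{TRUE})
#' @param ci_level pointwise interval level (default 0.95)
#' @param z_scale standardize the continuous predictors (alpha, Gini, bout
#'   count, age) to unit SD before fitting; coefficient curves are then per-SD
#'   effects. Default \code{FALSE} (natural scales)
#' @return a list of class \code{"dow_model_spec"}
#' @export
model_spec <- function(outcome = c("median_rt", "mean_correct"),
                       bout_class = c("SED", "LPA", "MVPA"),
                       K = 5, penalty_order = 2,
                       smoothing = c("REML", "fixed"),
                       lambda = NULL,
                       random_intercept = TRUE,
                       ci_level = 0.95,
                       z_scale = FALSE) {
  outcome <- match.arg(outcome)
  bout_class <- match.arg(bout_class)
  smoothing <- match.arg(smoothing)
  stopifnot(K >= 3, K <= 7, K == round(K),
            ci_level > 0, ci_level < 1,
            penalty_order >= 1)
  if (smoothing == "fixed" && is.null(lambda)) lambda <- 0
  structure(list(outcome = outcome, bout_class = bout_class, K = as.integer(K),
                 penalty_order = penalty_order, smoothing = smoothing,
                 lambda = lambda, random_intercept = isTRUE(random_intercept),
                 ci_level = ci_level, z_scale = isTRUE(z_scale)),
            class = "dow_model_spec")
}

# term names for a given bout class (order fixed: matches beta_0..beta_6,
# education contributing two indicator curves)
model_terms <- function(bout_class) {
  c("intercept",
    paste0("alpha_", bout_class),
    paste0("gini_", bout_class),
    paste0("nbouts_", bout_class),
    "age", "sex", "edu_college", "edu_advanced")
}

#' Build the design matrices for the varying-coefficient model
#'
#' Each covariate (including the constant 1) is multiplied column-wise with
#' the cyclic basis evaluated at the row's day of week, giving
#' \code{8 * K} fixed-effect columns, one circulant penalty block per curve,
#' and a subject grouping factor for the random intercept. Rows with a
#' missing outcome or missing required predictors are dropped (count
#' reported).
#'
#' @param observations analysis table from [build_analysis_table()] (or
#'   [cohort_table()]); must contain \code{subject_id}, \code{dow}, the
#'   outcome column, \code{alpha_/gini_/nbouts_<class>}, \code{age},
#'   \code{sex}, \code{edu_college}, \code{edu_advanced}
#' @param spec a [model_spec()]
#' @return list with elements \code{X} (n x 8K), \code{y}, \code{subject}
#'   (factor), \code{terms}, \code{blocks} (column indices per curve),
#'   \code{S} (penalty matrix per curve), \code{n_dropped}, \code{scales}
#' @export
build_design <- function(observations, spec) {
  stopifnot(inherits(spec, "dow_model_spec"))
  obs <- as.data.frame(observations)
  terms <- model_terms(spec$bout_class)
  covariate_cols <- c(spec$outcome, terms[-1], "subject_id", "dow")
  missing_cols <- setdiff(covariate_cols, names(obs))
  if (length(missing_cols))
    stop_input("build_design: observations lack columns: %s",
               paste(missing_cols, collapse = ", "))

  Z <- cbind(intercept = 1, as.matrix(obs[, terms[-1], drop = FALSE]))
  y <- obs[[spec$outcome]]
  keep <- is.finite(y) & rowSums(!is.finite(Z)) == 0
  n_dropped <- sum(!keep)
  obs <- obs[keep, , drop = FALSE]
  Z <- Z[keep, , drop = FALSE]
  y <- y[keep]
  if (!nrow(obs)) stop_input("build_design: no complete rows left")

  scales <- rep(1, length(terms))
  names(scales) <- terms
  if (spec$z_scale) {
    for (v in terms[2:5]) {   # alpha, gini, nbouts, age
      s <- stats::sd(Z[, v])
      if (is.finite(s) && s > 0) {
        Z[, v] <- Z[, v] / s
        scales[v] <- s
      }
    }
  }

  # warn on degenerate (constant) predictors; the penalty regularizes them
  degen <- vapply(terms[-1], function(v) stats::var(Z[, v]) < 1e-14, logical(1))
  if (any(degen))
    warning("build_design: constant predictor(s): ",
            paste(terms[-1][degen], collapse = ", "), call. = FALSE)

  B <- cyclic_basis(obs$dow, spec$K)
  X <- matrix(0, nrow(obs), length(terms) * spec$K)
  blocks <- vector("list", length(terms))
  names(blocks) <- terms
  for (j in seq_along(terms)) {
    idx <- (j - 1L) * spec$K + seq_len(spec$K)
    X[, idx] <- Z[, j] * B
    blocks[[j]] <- idx
  }
  colnames(X) <- paste(rep(terms, each = spec$K), rep(seq_len(spec$K), length(terms)), sep = ".")
  list(X = X, y = y, subject = factor(obs$subject_id), dow = obs$dow,
       terms = terms, blocks = blocks,
       S = cyclic_penalty(spec$K, spec$penalty_order),
       n_dropped = n_dropped, scales = scales)
}

# ---- REML machinery -------------------------------------------------------

# Restricted likelihood score for the penalized working model
#   y = C beta + e,  e ~ N(0, phi I),  beta ~ N(0, phi S_lambda^-)
# with S_lambda block diagonal: lambda_j * S per curve plus lambda_b * I on
# the subject-indicator block. phi is profiled out. Returns the function of
# log10(lambda) to minimize.
make_reml_score <- function(CtC, Cty, yty, pen_blocks, n) {
  Mp <- sum(vapply(pen_blocks, function(b) b$nulldim, numeric(1)))
  ldet_const <- sum(vapply(pen_blocks, function(b) b$ldet_pos, numeric(1)))
  ranks <- vapply(pen_blocks, function(b) b$rank, numeric(1))
  p <- nrow(CtC)
  function(loglam) {
    lam <- 10^loglam
    A <- CtC
    for (j in seq_along(pen_blocks)) {
      b <- pen_blocks[[j]]
      A[b$idx, b$idx] <- A[b$idx, b$idx] + lam[j] * b$S
    }
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) return(Inf)
    beta <- backsolve(R, backsolve(R, Cty, transpose = TRUE))
    P <- yty - sum(beta * Cty)        # RSS + penalty, by the normal equations
    if (!is.finite(P) || P <= 0) return(Inf)
    phi <- P / (n - Mp)
    ldetA <- 2 * sum(log(diag(R)))
    ldetS <- sum(ranks * log(lam)) + ldet_const
    0.5 * ((n - Mp) * (log(2 * pi * phi) + 1) + ldetA - ldetS)
  }
}

# Same restricted likelihood, but with the subject-intercept block eliminated
# analytically: for C = [X Z] with Z the subject indicators and penalty
# lambda_b I on its coefficients,
#   |C'C + S| = prod_i (n_i + lambda_b) * |X'X + S_x - T' W T|,
# where T = Z'X and W = diag(1/(n_i + lambda_b)). Each evaluation then costs
# one p_fix x p_fix Cholesky instead of one of size p_fix + n_subjects.
# Smoothing parameters come first in loglam; the subject lambda is last.
make_reml_score_ri <- function(XtX, Xty, T, Zty, ni, yty, sm_blocks, n) {
  Mp <- sum(vapply(sm_blocks, function(b) b$nulldim, numeric(1)))
  ldet_const <- sum(vapply(sm_blocks, function(b) b$ldet_pos, numeric(1)))
  ranks <- vapply(sm_blocks, function(b) b$rank, numeric(1))
  n_subj <- length(ni)
  function(loglam) {
    q <- length(loglam)
    lam <- 10^loglam[-q]
    lamb <- 10^loglam[q]
    w <- 1 / (ni + lamb)
    A <- XtX - crossprod(T * sqrt(w))
    for (j in seq_along(sm_blocks)) {
      b <- sm_blocks[[j]]
      A[b$idx, b$idx] <- A[b$idx, b$idx] + lam[j] * b$S
    }
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) return(Inf)
    r <- Xty - drop(crossprod(T, w * Zty))
    theta <- backsolve(R, backsolve(R, r, transpose = TRUE))
    b_hat <- w * (Zty - drop(T %*% theta))
    P <- yty - sum(theta * Xty) - sum(b_hat * Zty)
    if (!is.finite(P) || P <= 0) return(Inf)
    phi <- P / (n - Mp)
    ldetA <- sum(log(ni + lamb)) + 2 * sum(log(diag(R)))
    ldetS <- sum(ranks * log(lam)) + ldet_const + n_subj * log(lamb)
    0.5 * ((n - Mp) * (log(2 * pi * phi) + 1) + ldetA - ldetS)
  }
}

# golden-section refinement of a bracketed 1-d minimum; stops when the score
# stops changing (tol on the score, not the abscissa)
golden_refine <- function(f, a, b, f_best, x_best, tol = 1e-8, maxit = 40) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  for (it in seq_len(maxit)) {
    if (f1 <= f2) { b <- x2; x2 <- x1; f2 <- f1; x1 <- b - gr * (b - a); f1 <- f(x1) }
    else          { a <- x1; x1 <- x2; f1 <- f2; x2 <- a + gr * (b - a); f2 <- f(x2) }
    # golden search reuses the better endpoint, so convergence is judged on
    # the score gap across the bracket, not on iteration-to-iteration change
    if (is.finite(f1) && is.finite(f2) && abs(f1 - f2) < tol) break
  }
  if (f1 <= f2) { x <- x1; fx <- f1 } else { x <- x2; fx <- f2 }
  if (fx < f_best) list(x = x, f = fx) else list(x = x_best, f = f_best)
}

# coordinate descent over log10 smoothing parameters: coarse grid bracket per
# coordinate on the first pass, local bracket plus golden-section refinement
# afterwards; coordinates that have stopped moving are skipped. Deterministic.
optimize_reml <- function(score, q, init = NULL,
                          lower = -7, upper = 9, tol = 1e-5, max_cycles = 6) {
  warm <- !is.null(init)
  ll <- if (warm) clamp(init, lower, upper) else rep(1, q)
  best <- score(ll)
  if (!is.finite(best)) { warm <- FALSE; ll <- rep(3, q); best <- score(ll) }
  moved <- rep(Inf, q)
  cycles <- 0L
  for (cycle in seq_len(max_cycles)) {
    cycles <- cycle
    prev <- best
    for (j in seq_len(q)) {
      if (cycle > 2L && moved[j] < 1e-2) next
      grid <- if (cycle == 1L && !warm) seq(lower, upper, by = 2)
              else sort(unique(clamp(ll[j] + c(-0.75, 0, 0.75), lower, upper)))
      f1 <- function(v) { l2 <- ll; l2[j] <- v; score(l2) }
      fg <- vapply(grid, f1, numeric(1))
      k <- which.min(fg)
      a <- grid[max(1L, k - 1L)]; b <- grid[min(length(grid), k + 1L)]
      # early cycles only need a rough line minimum; the last passes polish
      # to the 1e-8 score tolerance
      gtol <- if (cycle < 3L) 1e-4 else 1e-8
      res <- if (fg[k] < best) golden_refine(f1, a, b, fg[k], grid[k], tol = gtol)
             else golden_refine(f1, a, b, best, ll[j], tol = gtol)
      if (res$f <= best) { moved[j] <- abs(res$x - ll[j]); ll[j] <- res$x; best <- res$f }
      else moved[j] <- 0
    }
    if (prev - best < tol) break
  }
  list(loglam = ll, score = best, cycles = cycles, converged = TRUE)
}

# ---- fitting --------------------------------------------------------------

#' Fit the day-of-week varying-coefficient model
#'
#' Penalized REML fit of the weekly varying-coefficient regression (see the
#' package vignette for the model). Returns estimated coefficient curves at
#' d = 1..7 with pointwise Bayesian intervals, a Wald-type test that each
#' whole curve is zero, effective degrees of freedom, variance components and
#' an adjusted R-squared.
#'
#' @param observations analysis table (one row per subject x day-of-week)
#' @param spec a [model_spec()]; alternatively pass \code{outcome} /
#'   \code{bout_class} via \code{...} to build one
#' @param lambda_init optional starting values for the log10 smoothing
#'   parameters (used to warm-start replicate loops)
#' @param ... arguments forwarded to [model_spec()] when \code{spec} is missing
#' @return object of class \code{"dow_fit"}: list with \code{curves} (tidy
#'   data.frame: term, d, estimate, se, lo, hi), \code{wald} (term, stat, df,
#'   p), \code{edf} per term, \code{adj_r2}, \code{sigma2} (residual),
#'   \code{sigma2_b} (random intercept), \code{lambda}, \code{n_obs},
#'   \code{n_subjects}, \code{n_dropped}, \code{fitted}, \code{residuals}
#' @export
fit_model <- function(observations, spec = NULL, lambda_init = NULL, ...) {
  if (is.null(spec)) spec <- model_spec(...)
  stopifnot(inherits(spec, "dow_model_spec"))
  des <- build_design(observations, spec)
  n <- length(des$y)
  n_subj <- nlevels(des$subject)
  dows_per_subj <- table(des$subject)
  if (n_subj < 10 || stats::median(dows_per_subj) < 2)
    stop_input("fit_model: need at least 10 subjects with >= 2 days of week each (have %d subjects)", n_subj)

  K <- spec$K
  terms <- des$terms
  q_sm <- length(terms)
  p_fix <- ncol(des$X)

  use_ri <- spec$random_intercept
  if (use_ri) {
    Zs <- stats::model.matrix(~ 0 + des$subject)
    C <- cbind(des$X, Zs)
  } else {
    C <- des$X
  }
  p <- ncol(C)
  CtC <- crossprod(C)
  Cty <- drop(crossprod(C, des$y))
  yty <- sum(des$y^2)

  ev_S <- eigen(des$S, symmetric = TRUE, only.values = TRUE)$values
  pos <- ev_S > max(ev_S) * 1e-10
  sm_blocks <- lapply(seq_along(terms), function(j)
    list(idx = des$blocks[[j]], S = des$S, rank = sum(pos),
         nulldim = K - sum(pos), ldet_pos = sum(log(ev_S[pos]))))
  pen_blocks <- sm_blocks
  if (use_ri)
    pen_blocks <- c(pen_blocks, list(list(idx = p_fix + seq_len(n_subj),
                                          S = diag(n_subj), rank = n_subj,
                                          nulldim = 0, ldet_pos = 0)))
  q_pen <- length(pen_blocks)

  sc <- if (use_ri) {
    make_reml_score_ri(XtX = CtC[seq_len(p_fix), seq_len(p_fix)],
                       Xty = Cty[seq_len(p_fix)],
                       T = t(CtC[seq_len(p_fix), p_fix + seq_len(n_subj)]),
                       Zty = Cty[p_fix + seq_len(n_subj)],
                       ni = as.numeric(table(des$subject)),
                       yty = yty, sm_blocks = sm_blocks, n = n)
  } else {
    make_reml_score(CtC, Cty, yty, pen_blocks, n)
  }

  if (spec$smoothing == "fixed") {
    lam_sm <- rep(spec$lambda, length.out = q_sm)
    # with fixed smoothing the intercept variance is still REML-estimated;
    # blocks fixed at lambda = 0 are genuinely unpenalized, so they count as
    # null space (fixed effects) in the restricted likelihood
    if (use_ri) {
      sm_fixed <- lapply(seq_len(q_sm), function(j) {
        b <- sm_blocks[[j]]
        if (lam_sm[j] == 0) { b$S <- matrix(0, K, K); b$rank <- 0; b$nulldim <- K; b$ldet_pos <- 0 }
        b
      })
      sc <- make_reml_score_ri(XtX = CtC[seq_len(p_fix), seq_len(p_fix)],
                               Xty = Cty[seq_len(p_fix)],
                               T = t(CtC[seq_len(p_fix), p_fix + seq_len(n_subj)]),
                               Zty = Cty[p_fix + seq_len(n_subj)],
                               ni = as.numeric(table(des$subject)),
                               yty = yty, sm_blocks = sm_fixed, n = n)
      f1 <- function(v) sc(c(ifelse(lam_sm == 0, 0, log10(lam_sm)), v))
      gg <- seq(-7, 9, by = 1)
      fg <- vapply(gg, f1, numeric(1))
      k <- which.min(fg)
      res <- golden_refine(f1, gg[max(1, k - 1)], gg[min(length(gg), k + 1)], fg[k], gg[k])
      lam <- c(lam_sm, 10^res$x)
      reml <- list(score = res$f, cycles = 1L, converged = TRUE)
    } else {
      lam <- lam_sm
      reml <- list(score = NA_real_, cycles = 0L, converged = TRUE)
    }
  } else {
    opt <- optimize_reml(sc, q_pen, init = lambda_init)
    lam <- 10^opt$loglam
    reml <- opt
  }

  A <- CtC
  for (j in seq_len(q_pen)) {
    b <- pen_blocks[[j]]
    if (lam[j] > 0) A[b$idx, b$idx] <- A[b$idx, b$idx] + lam[j] * b$S
  }
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    # unpenalized / rank-deficient boundary: ridge the diagonal minimally
    A <- A + diag(max(diag(A)) * 1e-10, p)
    R <- chol(A)
  }
  beta <- backsolve(R, backsolve(R, Cty, transpose = TRUE))
  Ainv <- chol2inv(R)
  Fh <- Ainv %*% CtC                      # influence map coef->coef
  edf_col <- diag(Fh)
  edf1_col <- 2 * edf_col - rowSums(Fh * t(Fh))   # diag(2F - FF)
  Mp <- sum(vapply(seq_len(q_pen), function(j) {
    b <- pen_blocks[[j]]
    if (lam[j] == 0) length(b$idx) else b$nulldim
  }, numeric(1)))
  P <- yty - sum(beta * Cty)
  phi <- P / (n - Mp)
  Vb <- phi * Ainv

  fitted <- drop(C %*% beta)
  resid <- des$y - fitted
  rss <- sum(resid^2)
  edf_tot <- sum(edf_col)
  tss <- sum((des$y - mean(des$y))^2)
  adj_r2 <- 1 - (rss / max(n - edf_tot, 1)) / (tss / (n - 1))

  Bg <- cyclic_basis(1:7, K)
  zq <- stats::qnorm(1 - (1 - spec$ci_level) / 2)
  curves <- vector("list", q_sm)
  wald <- vector("list", q_sm)
  edf_term <- numeric(q_sm)
  for (j in seq_len(q_sm)) {
    idx <- des$blocks[[j]]
    # under z_scale the curves are reported per predictor SD (standardized
    # effects); the scale factors are kept alongside for interpretation
    th <- beta[idx]
    Vj <- Vb[idx, idx]
    f <- drop(Bg %*% th)
    Vf <- Bg %*% Vj %*% t(Bg)
    se <- sqrt(pmax(diag(Vf), 0))
    edf_term[j] <- sum(edf_col[idx])
    r_j <- min(K, max(1, sum(edf1_col[idx])))
    wt <- wald_test(f, Vf, rank = r_j)
    curves[[j]] <- data.frame(term = terms[j], d = 1:7, estimate = f, se = se,
                              lo = f - zq * se, hi = f + zq * se)
    wald[[j]] <- data.frame(term = terms[j], stat = wt$stat, df = wt$df, p = wt$p)
  }
  curves <- do.call(rbind, curves)
  wald <- do.call(rbind, wald)
  rownames(curves) <- rownames(wald) <- NULL
  names(edf_term) <- terms

  lam_named <- lam[seq_len(q_sm)]
  names(lam_named) <- terms
  sigma2_b <- if (use_ri) phi / lam[q_pen] else NA_real_
  edf_ri <- if (use_ri) sum(edf_col[p_fix + seq_len(n_subj)]) else 0

  structure(list(spec = spec, curves = curves, wald = wald,
                 edf = edf_term, edf_subject = edf_ri, edf_total = edf_tot,
                 adj_r2 = adj_r2, sigma2 = phi, sigma2_b = sigma2_b,
                 lambda = lam_named,
                 lambda_subject = if (use_ri) lam[q_pen] else NA_real_,
                 loglam = log10(pmax(lam, 1e-300)),
                 reml = reml, n_obs = n, n_subjects = n_subj,
                 n_dropped = des$n_dropped,
                 fitted = fitted, residuals = resid, y = des$y,
                 subject = des$subject, dow = des$dow,
                 coef = beta, blocks = des$blocks, scales = des$scales),
            class = "dow_fit")
}

#' Wald-type test that a coefficient curve is zero
#'
#' Computes \eqn{T = \hat\theta' V^{+} \hat\theta} with a rank-aware
#' pseudo-inverse of the covariance and refers \code{T} to a chi-square upper
#' tail. When \code{rank} is \code{NULL} the numerical rank of \code{V} is
#' used. For penalized curves, [fit_model()] passes the term's (alternative)
#' effective degrees of freedom as \code{rank}; the pseudo-inverse then
#' retains only the \code{floor(rank)} leading eigen-directions plus a
#' fractional weight on the next one, which keeps the test approximately
#' calibrated under shrinkage (the smooth-term test of the mgcv family).
#'
#' @param theta estimated coefficient (or curve value) vector
#' @param V its covariance matrix
#' @param rank test rank: \code{NULL} for the numerical rank of \code{V}, or a
#'   (possibly fractional) effective degrees of freedom
#' @param tol relative eigenvalue tolerance for the numerical rank
#' @return list with \code{stat}, \code{df}, \code{p}
#' @export
wald_test <- function(theta, V, rank = NULL, tol = 1e-9) {
  theta <- as.numeric(theta)
  V <- as.matrix(V)
  ev <- eigen(V, symmetric = TRUE)
  lam <- ev$values
  mx <- max(lam, 0)
  if (mx <= 0) {
    warning("wald_test: zero-rank covariance; p = 1", call. = FALSE)
    return(list(stat = 0, df = 0, p = 1))
  }
  keep <- lam > tol * mx
  nr <- sum(keep)
  r <- if (is.null(rank)) nr else min(rank, nr)
  r <- max(r, min(1, nr))
  z2 <- drop(crossprod(ev$vectors, theta))^2 / lam
  k <- floor(r + 1e-8)
  nu <- r - k
  stat <- sum(z2[seq_len(k)])
  if (nu > 1e-6 && k < nr) stat <- stat + nu * z2[k + 1]
  df <- k + if (nu > 1e-6 && k < nr) nu else 0
  p <- if (df <= 0) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(stat = stat, df = df, p = p)
}

#' Mean absolute effect size of a fitted coefficient curve
#'
#' \eqn{(1/7) \sum_d |\hat\beta_j(d)|}: the average absolute height of the
#' curve over the seven week days, the summary used to report effect
#' magnitudes for the distribution indices.
#'
#' @param fit a \code{"dow_fit"} object, or a curve data.frame with columns
#'   \code{term, d, estimate}
#' @param term curve name, e.g. \code{"gini_MVPA"}; may be omitted when
#'   \code{fit} is a single-term curve data.frame
#' @return scalar mean absolute effect
#' @export
mean_abs_effect <- function(fit, term = NULL) {
  curves <- if (inherits(fit, "dow_fit")) fit$curves else as.data.frame(fit)
  if (!is.null(term)) curves <- curves[curves$term == term, , drop = FALSE]
  if (!nrow(curves)) stop_input("mean_abs_effect: no rows for term '%s'", term %||% "<all>")
  if (length(unique(curves$term)) != 1L)
    stop_input("mean_abs_effect: specify a single term")
  mean(abs(curves$estimate))
}

#' @export
print.dow_fit <- function(x, ...) {
  cat(sprintf("Day-of-week varying-coefficient fit: %s ~ %s indices\n",
              x$spec$outcome, x$spec$bout_class))
  cat(sprintf("  n = %d rows, %d subjects (%d dropped); K = %d, smoothing = %s\n",
              x$n_obs, x$n_subjects, x$n_dropped, x$spec$K, x$spec$smoothing))
  cat(sprintf("  sigma^2 = %.4g; subject intercept var = %.4g; adj. R^2 = %.3f\n",
              x$sigma2, x$sigma2_b, x$adj_r2))
  cat("  Wald-type curve tests:\n")
  w <- x$wald
  w$p <- format.pval(w$p, digits = 3)
  w$stat <- round(w$stat, 2); w$df <- round(w$df, 2)
  print(w, row.names = FALSE)
  invisible(x)
}

#' @export
summary.dow_fit <- function(object, ...) {
  print(object)
  cat("\nMean absolute effects:\n")
  for (tm in unique(object$curves$term))
    cat(sprintf("  %-14s %8.4g\n", tm, mean_abs_effect(object, tm)))
  invisible(object)
}

#' Plot fitted coefficient curves with pointwise bands
#'
#' One panel per requested term: estimate over d = 1..7 (Sunday..Saturday)
#' with the shaded pointwise interval and a zero reference line.
#'
#' @param x a \code{"dow_fit"}
#' @param terms curve names to plot (default: the three bout-distribution
#'   predictors of the fitted class)
#' @param ... ignored
#' @export
plot.dow_fit <- function(x, terms = NULL, ...) {
  if (is.null(terms))
    terms <- paste0(c("gini_", "alpha_", "nbouts_"), x$spec$bout_class)
  terms <- intersect(terms, unique(x$curves$term))
  old <- graphics::par(mfrow = c(1, length(terms)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (tm in terms) {
    cv <- x$curves[x$curves$term == tm, ]
    ylim <- range(cv$lo, cv$hi, 0)
    plot(cv$d, cv$estimate, type = "n", ylim = ylim,
         xlab = "day of week (1 = Sun)", ylab = "effect", main = tm)
    graphics::polygon(c(cv$d, rev(cv$d)), c(cv$lo, rev(cv$hi)),
                      col = grDevices::grey(0.85), border = NA)
    graphics::lines(cv$d, cv$estimate, lwd = 2)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}
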