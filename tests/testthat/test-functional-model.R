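test_that("the cyclic basis is periodic, partition-of-unity, and saturates at K = 7", {
  for (K in c(3, 5, 7)) {
    d <- seq(0.5, 7.5, by = 0.25)
    B <- cyclic_basis(d, K)
    expect_equal(rowSums(B), rep(1, length(d)), tolerance = 1e-12)
    expect_equal(cyclic_basis(d, K), cyclic_basis(d + 7, K), tolerance = 1e-12)
  }
  expect_equal(qr(cyclic_basis(1:7, 7))$rank, 7)
  # constant exactly representable: projecting 1 leaves no residual
  B <- cyclic_basis(1:7, 5)
  resid <- rep(1, 7) - B %*% qr.solve(B, rep(1, 7))
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("the circulant penalty annihilates constants and has rank K - 1", {
  for (K in c(4, 5, 7)) {
    S <- cyclic_penalty(K)
    expect_equal(max(abs(S %*% rep(1, K))), 0)
    expect_equal(qr(S)$rank, K - 1)
    expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  }
})

test_that("the design is the covariate-by-basis product with one penalty block per curve", {
  ct <- cohort_table(sim_config(n_subjects = 15), seed = 3)
  spec <- model_spec("median_rt", "SED", K = 5)
  des <- build_design(ct$observations, spec)
  expect_equal(ncol(des$X), 8 * 5)
  expect_equal(length(des$blocks), 8)
  # one row assembled by hand
  i <- 11
  row <- ct$observations[i, ]
  z <- c(1, row$alpha_SED, row$gini_SED, row$nbouts_SED, row$age, row$sex,
         row$edu_college, row$edu_advanced)
  expect_equal(des$X[i, ], as.vector(outer(drop(cyclic_basis(row$dow, 5)), z)),
               ignore_attr = TRUE, tolerance = 1e-12)
  # missing index rows are dropped with a count
  obs2 <- ct$observations
  obs2$gini_SED[1:3] <- NA
  expect_equal(build_design(obs2, spec)$n_dropped, 3)
})

test_that("saturated unpenalized fits equal day-stratified OLS", {
  ct <- cohort_table(sim_config(n_subjects = 60), seed = 42)
  obs <- ct$observations
  f <- fit_model(obs, model_spec("median_rt", "SED", K = 7,
                                 smoothing = "fixed", lambda = 0,
                                 random_intercept = FALSE))
  for (d in 1:7) {
    m <- lm(median_rt ~ alpha_SED + gini_SED + nbouts_SED + age + sex +
              edu_college + edu_advanced, data = obs[obs$dow == d, ])
    co <- coef(m); names(co)[1] <- "intercept"
    for (tm in names(co)) {
      expect_equal(f$curves$estimate[f$curves$term == tm & f$curves$d == d],
                   unname(co[tm]), tolerance = 1e-6)
    }
  }
})

test_that("the saturated REML fit matches lme4 on coefficients and variance components", {
  ct <- cohort_table(sim_config(n_subjects = 60), seed = 42)
  obs <- ct$observations
  f <- fit_model(obs, model_spec("median_rt", "SED", K = 7,
                                 smoothing = "fixed", lambda = 0))
  obs$dw <- factor(obs$dow)
  m <- lme4::lmer(median_rt ~ 0 + dw + dw:(alpha_SED + gini_SED + nbouts_SED +
                                             age + sex + edu_college + edu_advanced) +
                    (1 | subject_id), data = obs, REML = TRUE)
  expect_equal(f$sigma2, sigma(m)^2, tolerance = 1e-3)
  expect_equal(f$sigma2_b, unname(lme4::VarCorr(m)$subject_id[1]), tolerance = 1e-3)
  fe <- lme4::fixef(m)
  for (d in c(1, 4, 7)) {
    expect_equal(f$curves$estimate[f$curves$term == "gini_SED" & f$curves$d == d],
                 unname(fe[paste0("dw", d, ":gini_SED")]), tolerance = 1e-3)
  }
})

test_that("fixed smoothing without a random intercept solves penalized least squares", {
  ct <- cohort_table(sim_config(n_subjects = 30), seed = 8)
  spec <- model_spec("median_rt", "SED", K = 5, smoothing = "fixed",
                     lambda = 50, random_intercept = FALSE)
  f <- fit_model(ct$observations, spec)
  des <- build_design(ct$observations, spec)
  S <- matrix(0, 40, 40)
  for (b in des$blocks) S[b, b] <- S[b, b] + 50 * cyclic_penalty(5)
  theta <- solve(crossprod(des$X) + S, crossprod(des$X, des$y))
  B <- cyclic_basis(1:7, 5)
  for (j in seq_along(des$terms)) {
    expect_equal(f$curves$estimate[f$curves$term == des$terms[j]],
                 drop(B %*% theta[des$blocks[[j]]]), tolerance = 1e-6)
  }
})

test_that("wald_test covers the degenerate and scalar reference cases", {
  w0 <- wald_test(rep(0, 5), diag(5))
  expect_equal(w0$stat, 0)
  expect_equal(w0$p, 1)

  # scalar case: chi-square(1) equals the squared two-sided normal test
  th <- 1.7; se <- 0.6
  w <- wald_test(th, matrix(se^2))
  expect_equal(w$stat, (th / se)^2)
  expect_equal(w$df, 1)
  expect_equal(w$p, 2 * pnorm(-abs(th / se)), tolerance = 1e-12)

  expect_warning(wz <- wald_test(c(1, 1), matrix(0, 2, 2)), "zero-rank")
  expect_equal(wz$p, 1)

  # fractional rank interpolates between integer chi-squares
  V <- diag(c(4, 1, 0.25))
  th3 <- c(2, 1, 0.5)
  w15 <- wald_test(th3, V, rank = 1.5)
  expect_equal(w15$stat, 1 + 0.5 * 1)
  expect_equal(w15$df, 1.5)
})

test_that("mean absolute effects summarize curve magnitude", {
  cv <- data.frame(term = "gini_SED", d = 1:7, estimate = rep(-2, 7))
  expect_equal(mean_abs_effect(cv), 2)
  cv$estimate <- 0
  expect_equal(mean_abs_effect(cv), 0)
  ct <- cohort_table(sim_config(n_subjects = 15), seed = 3)
  f <- fit_model(ct$observations, model_spec("median_rt", "SED"))
  est <- f$curves$estimate[f$curves$term == "gini_SED"]
  expect_equal(mean_abs_effect(f, "gini_SED"), mean(abs(est)))
})

test_that("predictions are invariant to affine recoding of sex in the saturated fit", {
  ct <- cohort_table(sim_config(n_subjects = 40), seed = 15)
  obs <- ct$observations
  spec <- model_spec("median_rt", "SED", K = 7, smoothing = "fixed",
                     lambda = 0, random_intercept = FALSE)
  f1 <- fit_model(obs, spec)
  obs2 <- obs
  obs2$sex <- obs$sex + 1       # 1/2 coding
  f2 <- fit_model(obs2, spec)
  expect_equal(f2$fitted, f1$fitted, tolerance = 1e-6)
  # non-intercept, non-sex curves unchanged; intercept absorbs the shift
  for (tm in c("gini_SED", "alpha_SED", "age", "sex")) {
    expect_equal(f2$curves$estimate[f2$curves$term == tm],
                 f1$curves$estimate[f1$curves$term == tm], tolerance = 1e-5)
  }
})

test_that("z-scaling rescales curves onto per-SD units without changing fits", {
  ct <- cohort_table(sim_config(n_subjects = 40), seed = 16)
  f_raw <- fit_model(ct$observations, model_spec("median_rt", "SED", K = 7,
                                                 smoothing = "fixed", lambda = 0,
                                                 random_intercept = FALSE))
  f_z <- fit_model(ct$observations, model_spec("median_rt", "SED", K = 7,
                                               smoothing = "fixed", lambda = 0,
                                               random_intercept = FALSE, z_scale = TRUE))
  expect_equal(f_z$fitted, f_raw$fitted, tolerance = 1e-6)
  s <- sd(ct$observations$gini_SED)
  expect_equal(f_z$curves$estimate[f_z$curves$term == "gini_SED"],
               f_raw$curves$estimate[f_raw$curves$term == "gini_SED"] * s,
               tolerance = 1e-5)
})

test_that("underpowered inputs are refused", {
  ct <- cohort_table(sim_config(n_subjects = 5), seed = 3)
  expect_error(suppressWarnings(fit_model(ct$observations, model_spec("median_rt", "SED"))),
               "at least 10 subjects")
})
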