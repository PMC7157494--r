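test_that("Rubin pooling reproduces hand arithmetic", {
  cmb <- rubin_combine(c(0, 2), c(1, 1))
  expect_equal(cmb$qbar, 1)
  expect_equal(cmb$b, 2)
  expect_equal(cmb$ubar, 1)
  expect_equal(cmb$t_var, 1 + 1.5 * 2)       # = 4
  expect_equal(cmb$df, (2 - 1) * (1 + 1 / 3)^2)  # = 16/9
  expect_equal(cmb$se, 2)
})

test_that("identical imputations collapse to the single-fit answer", {
  cmb <- rubin_combine(rep(0.7, 5), rep(0.04, 5))
  expect_equal(cmb$qbar, 0.7)
  expect_equal(cmb$b, 0)
  expect_equal(cmb$t_var, 0.04)
  expect_true(is.infinite(cmb$df))
})

test_that("Barnard-Rubin adjusted df never exceeds the classic df", {
  cmb <- rubin_combine(c(0, 2), c(1, 1))
  adj <- rubin_combine(c(0, 2), c(1, 1), dfcom = 50)
  expect_lt(adj$df, cmb$df)
  # adjusted df is bounded by the complete-data df
  expect_lt(adj$df, 50)
  # equal-estimate edge case keeps the normal reference
  expect_true(is.infinite(rubin_combine(c(1, 1), c(1, 1), dfcom = 50)$df))
})

test_that("pooling is invariant to imputation order and validates input", {
  est <- c(0.2, -0.1, 0.4, 0.05); va <- c(0.01, 0.02, 0.015, 0.012)
  a <- rubin_combine(est, va)
  b <- rubin_combine(rev(est), rev(va))
  expect_equal(a[c("qbar", "t_var", "df", "p_value")],
               b[c("qbar", "t_var", "df", "p_value")])
  expect_error(rubin_combine(c(1, 2), 1), "same length")
  expect_error(rubin_combine(1, 1), "at least 2")
})

test_that("total variance never falls below the within-imputation variance", {
  set.seed(10)
  for (i in 1:20) {
    est <- rnorm(7); va <- rexp(7)
    cmb <- rubin_combine(est, va)
    expect_gte(cmb$t_var, cmb$ubar)
  }
})

test_that("a complete panel yields M identical copies", {
  sim <- simulate_trial(design_config(15, n_weeks = 6, seed = 44))
  imp <- impute_daily(sim$daily, M = 3, baseline = sim$baseline, seed = 2)
  expect_length(imp, 3)
  expect_identical(imp[[1]], sim$daily)
  expect_identical(imp[[2]], sim$daily)
})

test_that("imputed values honour scale bounds and are stochastic", {
  sim <- simulate_trial(design_config(60, n_weeks = 10, seed = 50),
                        missingness = ihs_missingness())
  imp <- impute_daily(sim$daily, M = 2, baseline = sim$baseline, seed = 3)
  for (d in imp) {
    expect_false(anyNA(d$mood))
    expect_true(all(d$mood >= 1 & d$mood <= 10 & d$mood == round(d$mood)))
    expect_true(all(d$steps >= 0))
    expect_true(all(d$sleep_minutes >= 0 & d$sleep_minutes <= 1440))
  }
  # draws, not conditional means: the two imputations differ where missing
  miss <- is.na(sim$daily$steps)
  expect_gt(mean(imp[[1]]$steps[miss] != imp[[2]]$steps[miss]), 0.95)
  # observed values are untouched
  expect_identical(imp[[1]]$mood[!is.na(sim$daily$mood)],
                   sim$daily$mood[!is.na(sim$daily$mood)])
})

test_that("pooled moderation estimate tracks the complete-data fit under MCAR", {
  truth <- linear_truth()
  panel_full <- sim_mood_panel(150, n_weeks = 26, seed = 61, truth = truth)
  fit_full <- fit_wcls(build_design_matrix(panel_full, mode = "binary"))
  # rebuild the daily table and delete 20% of days completely at random
  cfg <- design_config(150, n_weeks = 26, seed = 61)
  asg <- randomize_weekly(cfg)
  out <- generate_outcomes(asg, truth, seed = 61, measure = "mood")
  daily <- out$daily
  daily$arm <- asg$arm[rep(seq_len(nrow(asg)), each = 7L)]
  daily$day_of_week <- daily$study_day - (daily$week_index - 1L) * 7L
  set.seed(62)
  daily$mood[runif(nrow(daily)) < 0.2] <- NA
  bl <- data.frame(participant_id = unique(daily$participant_id),
                   mood = as.numeric(out$baseline))
  imp <- impute_daily(daily, M = 5, baseline = bl, measures = "mood",
                      seed = 63)
  fits <- lapply(imp, function(d)
    fit_wcls(build_design_matrix(weekly_panel(d, "mood", baseline = bl),
                                 mode = "binary")))
  pooled <- pool_wcls(fits)
  b_full <- fit_full$coefficients[["trt:moderator"]]
  ct <- test_coefficient(pooled, "trt:moderator")
  expect_lt(abs(ct$estimate - b_full), 3 * ct$se)
  # pooled SE at least the average within-imputation SE
  within <- mean(sapply(fits, function(f)
    sqrt(f$vcov["trt:moderator", "trt:moderator"])))
  expect_gte(ct$se, within)
})
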