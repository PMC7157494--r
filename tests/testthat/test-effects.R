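test_that("mood effect curve reproduces the reported endpoint arithmetic", {
  # slope through (3, 0.19) and (9, -0.12) is -0.31/6 = -0.0517 -> -0.052
  b1 <- (-0.12 - 0.19) / (9 - 3)
  expect_equal(round(b1, 3), -0.052)
  b0 <- 0.19 - b1 * 3
  curve <- effect_curve(make_fit(b0, b1), "mood", c(3, 9))
  expect_equal(round(curve$effect, 2), c(0.19, -0.12))
})

test_that("zero slope gives a flat curve at the intercept", {
  curve <- effect_curve(make_fit(0.27, 0), "mood", 1:9)
  expect_true(all(curve$effect == 0.27))
  expect_true(is.na(attr(curve, "crossing")))
})

test_that("the crossing point solves b0 + b1 g(m) = 0 on each scale", {
  c1 <- effect_curve(make_fit(0.345, -0.0516667), "mood", 3:9)
  m_star <- attr(c1, "crossing")
  expect_equal(0.345 - 0.0516667 * m_star, 0, tolerance = 1e-12)
  c2 <- effect_curve(make_fit(4.01705, -0.039, category = "activity",
                              transform = "sqrt"),
                     "activity", c(5625, 12100))
  expect_equal(4.01705 - 0.039 * sqrt(attr(c2, "crossing")), 0,
               tolerance = 1e-9)
})

test_that("sqrt retransformation reproduces the reported step effects", {
  # intercept calibrated so the natural effect is +165 steps at 5625
  delta <- calibrate_sqrt_delta(165, 5625)
  b0 <- delta + 0.039 * sqrt(5625)
  curve <- effect_curve(make_fit(b0, -0.039, category = "activity",
                                 transform = "sqrt"), "activity",
                        c(5625, 12100))
  expect_equal(round(curve$effect_natural), c(165, -60))
})

test_that("sqrt retransformation reproduces the reported sleep effects", {
  # +8 minutes at 5 h of previous sleep
  delta <- calibrate_sqrt_delta(8, 300)
  b0 <- delta + 0.075 * sqrt(300)
  curve <- effect_curve(make_fit(b0, -0.075, category = "sleep",
                                 transform = "sqrt"), "sleep", c(300, 480))
  expect_equal(round(curve$effect_natural), c(8, -5))
})

test_that("retransformation is inverse-consistent and anchored", {
  expect_equal(retransform_sqrt(0, c(0, 100, 5625)), c(0, 0, 0))
  for (m in c(1, 300, 5625, 12100)) {
    for (e in c(-50, -5, 0.5, 8, 165)) {
      if (m + e < 0) next
      expect_equal(retransform_sqrt(calibrate_sqrt_delta(e, m), m), e,
                   tolerance = 1e-9)
    }
  }
  expect_error(retransform_sqrt(1, -4), ">= 0")
  expect_error(calibrate_sqrt_delta(-400, 300), ">= 0")
})

test_that("natural-scale sign change coincides with the analysis-scale one", {
  b0 <- calibrate_sqrt_delta(8, 300) + 0.075 * sqrt(300)
  grid <- seq(200, 600, by = 1)
  curve <- effect_curve(make_fit(b0, -0.075, transform = "sqrt"),
                        "mood", grid)
  sign_a <- sign(curve$effect)
  sign_n <- sign(curve$effect_natural)
  expect_identical(sign_a, sign_n)
  expect_true(any(sign_a > 0) && any(sign_a < 0))
})

test_that("standardized effect sizes reproduce the reported ratios", {
  expect_equal(standardized_effect(165, 3285), 0.05)
  expect_equal(standardized_effect(-60, 3285), -0.02)
  expect_equal(standardized_effect(8, 75), 0.11)
  expect_equal(standardized_effect(-5, 75), -0.07)
  expect_equal(standardized_effect(0, 1.43), 0)
  expect_error(standardized_effect(1, 0), "> 0")
})

test_that("monotone decrease in the moderator over the observed step range", {
  # for small b1 < 0 the natural-scale curve is decreasing throughout the
  # cohort's moderator range (it can turn over far below it)
  b0 <- calibrate_sqrt_delta(165, 5625) + 0.039 * 75
  grid <- seq(3000, 16000, by = 500)
  curve <- effect_curve(make_fit(b0, -0.039, transform = "sqrt"),
                        "mood", grid)
  expect_true(all(diff(curve$effect_natural) < 0))
})

test_that("exploratory curves coincide under shared truth and bracket the pooled line", {
  shared <- linear_truth(
    b0 = c(activity = 0.3, sleep = 0.3, mood = 0.3),
    b1 = c(activity = -0.05, sleep = -0.05, mood = -0.05))
  panel <- sim_mood_panel(600, n_weeks = 26, seed = 71, truth = shared)
  fit <- fit_wcls(build_design_matrix(panel))
  bfit <- fit_wcls(build_design_matrix(panel, mode = "binary"))
  grid <- 3:9
  cur <- exploratory_curves(fit, grid, binary_fit = bfit)
  wide <- split(cur, cur$category)
  # identical truth: three category curves agree within CI half-widths
  for (g in seq_along(grid)) {
    effs <- sapply(wide[ACTIVE_ARMS], function(d) d$effect[g])
    hw <- max(sapply(wide[ACTIVE_ARMS], function(d) 1.96 * d$se[g]))
    expect_lt(diff(range(effs)), 2 * hw)
    # pooled line inside (a small tolerance around) the category hull
    pool_g <- wide$pooled$effect[g]
    expect_gte(pool_g, min(effs) - 0.02)
    expect_lte(pool_g, max(effs) + 0.02)
  }
})

test_that("report rendering is tabular, complete and deterministic", {
  panel <- sim_mood_panel(40, n_weeks = 8, seed = 81)
  fit <- fit_wcls(build_design_matrix(panel))
  grid <- 3:9
  cur <- exploratory_curves(fit, grid)
  tmp1 <- tempfile(fileext = ".csv"); tmp2 <- tempfile(fileext = ".csv")
  p <- render_report(cur, panel, tmp1)
  expect_s3_class(p, "ggplot")
  tab <- read.csv(tmp1)
  expect_equal(nrow(tab), length(grid) * 3)
  render_report(cur, panel, tmp2)
  expect_identical(readLines(tmp1), readLines(tmp2))
  expect_error(render_report(cur, panel[0, ], tempfile()), "empty")
})

test_that("a grid outside the plausible range warns but still evaluates", {
  expect_warning(
    effect_curve(make_fit(0.3, -0.05), "mood", c(0.5, 12),
                 grid_range = c(1, 10)),
    "plausible")
})
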