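test_that("noiseless model data are recovered to machine precision", {
  set.seed(41)
  n <- 60
  arm <- sample(ARM_LEVELS, n, replace = TRUE)
  m <- rnorm(n, 7, 1)
  base <- rnorm(n, 7, 1)
  zc <- outer(arm, ACTIVE_ARMS, "==") - 0.25
  beta <- c(2, 0.3, 0.5, 0.31, 0.39, 0.345, -0.052, -0.075, -0.039)
  X <- cbind(1, base, m, zc, zc * m)
  y <- drop(X %*% beta)
  panel <- data.frame(participant_id = rep(1:10, each = 6),
                      week = rep(1:6, 10),
                      arm = factor(arm, ARM_LEVELS), y = y,
                      moderator = m, baseline_y = base)
  fit <- fit_wcls(build_design_matrix(panel, controls = "baseline_y"))
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-10)
})

test_that("duplicating every cluster halves the sandwich covariance exactly", {
  panel <- sim_mood_panel(40, n_weeks = 8, seed = 5)
  fit <- fit_wcls(build_design_matrix(panel))
  dup <- panel
  dup$participant_id <- dup$participant_id + max(panel$participant_id)
  both <- rbind(panel, dup)
  attr(both, "measure") <- attr(panel, "measure")
  attr(both, "transform") <- attr(panel, "transform")
  fit2 <- fit_wcls(build_design_matrix(both))
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_lt(max(abs(fit2$vcov - fit$vcov / 2)), 1e-10)
})

test_that("centered fit matches uncentered interaction regression after reparameterization", {
  # small instance; the saturated centered and uncentered codings span the
  # same space, so b0k/b1k agree exactly and the moderator main effect maps
  # as a1_centered = a1_uncentered + sum_k p_k b1k
  panel <- sim_mood_panel(10, n_weeks = 4, seed = 13)
  panel <- panel[stats::complete.cases(panel), ]
  attr(panel, "measure") <- "mood"
  fit <- fit_wcls(build_design_matrix(panel, controls = "baseline_y"))
  lmf <- stats::lm(
    y ~ baseline_y + moderator + I(arm == "activity") + I(arm == "sleep") +
      I(arm == "mood") + I((arm == "activity") * moderator) +
      I((arm == "sleep") * moderator) + I((arm == "mood") * moderator),
    data = panel)
  cb <- coef(lmf)
  expect_equal(unname(cb[4:6]),
               unname(fit$coefficients[paste0("trt_", ACTIVE_ARMS)]),
               tolerance = 1e-9)
  b1_unc <- unname(cb[7:9])
  expect_equal(b1_unc,
               unname(fit$coefficients[paste0("trt_", ACTIVE_ARMS,
                                              ":moderator")]),
               tolerance = 1e-9)
  expect_equal(unname(cb["moderator"]) + 0.25 * sum(b1_unc),
               unname(fit$coefficients["moderator"]), tolerance = 1e-9)
})

test_that("cluster sandwich agrees with an independent implementation", {
  panel <- sim_mood_panel(30, n_weeks = 6, seed = 19)
  des <- build_design_matrix(panel)
  fit <- fit_wcls(des)
  Xs <- des$X[, -1]
  colnames(Xs) <- paste0("v", seq_len(ncol(Xs)))  # syntactic names for lm
  df <- data.frame(y = des$y, Xs)
  lmf <- stats::lm(y ~ ., data = df)
  vc <- sandwich::vcovCL(lmf, cluster = des$cluster, type = "HC0",
                         cadjust = FALSE)
  expect_equal(unname(vc[colnames(Xs), colnames(Xs)]),
               unname(fit$vcov[-1, -1]), tolerance = 1e-8)
})

test_that("estimates are invariant to row order and cluster relabeling", {
  panel <- sim_mood_panel(30, n_weeks = 6, seed = 29)
  fit <- fit_wcls(build_design_matrix(panel))
  shuf <- panel[sample(nrow(panel)), ]
  attr(shuf, "measure") <- "mood"; attr(shuf, "transform") <- "none"
  fit2 <- fit_wcls(build_design_matrix(shuf))
  expect_equal(fit$coefficients, fit2$coefficients, tolerance = 1e-10)
  expect_equal(fit$vcov, fit2$vcov, tolerance = 1e-9)
  relab <- panel
  relab$participant_id <- match(relab$participant_id,
                                sample(unique(relab$participant_id)))
  attr(relab, "measure") <- "mood"; attr(relab, "transform") <- "none"
  fit3 <- fit_wcls(build_design_matrix(relab))
  expect_equal(fit$coefficients, fit3$coefficients, tolerance = 1e-10)
})

test_that("rank deficiency names the collinear column, single cluster errors", {
  panel <- sim_mood_panel(10, n_weeks = 4, seed = 3)
  panel$dup <- panel$moderator
  expect_error(
    fit_wcls(build_design_matrix(panel, controls = c("baseline_y", "dup"))),
    "rank deficient")
  one <- panel[panel$participant_id == 1, ]
  attr(one, "measure") <- "mood"
  expect_error(fit_wcls(build_design_matrix(one, controls = NULL)),
               "at least 2")
})

test_that("coefficient tests follow the normal reference arithmetic", {
  fit <- make_fit(0.345, -0.052)
  fit$vcov[2, 2] <- 0.014^2
  ct <- test_coefficient(fit, "trt_mood:moderator")
  expect_equal(ct$statistic, -0.052 / 0.014, tolerance = 1e-12)
  expect_equal(ct$p_value, 2 * pnorm(-0.052 / 0.014), tolerance = 1e-12)
  expect_equal(ct$p_value, 2.04e-4, tolerance = 0.01)
  expect_equal(unname(ct$ci),
               c(-0.052 - 1.96 * 0.014, -0.052 + 1.96 * 0.014))
  # zero estimate: p = 1, CI symmetric about 0
  fit0 <- make_fit(0, 0)
  fit0$vcov[2, 2] <- 0.014^2
  ct0 <- test_coefficient(fit0, "trt_mood:moderator")
  expect_equal(ct0$p_value, 1)
  expect_equal(sum(ct0$ci), 0)
  expect_error(test_coefficient(fit, "nope"), "no coefficient")
})

test_that("the t reference option uses clusters minus parameters df", {
  panel <- sim_mood_panel(25, n_weeks = 6, seed = 7)
  fit <- fit_wcls(build_design_matrix(panel))
  ct <- test_coefficient(fit, "trt_mood:moderator", reference = "t")
  df <- fit$n_clusters - length(fit$coefficients)
  expect_equal(ct$p_value, 2 * pt(-abs(ct$statistic), df))
  expect_gt(ct$ci[["upper"]] - ct$ci[["lower"]],
            2 * 1.96 * ct$se)  # t CI is wider
})
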