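#' Ground-truth parameters for the outcome generator
#'
#' The generator mirrors the weekly moderation model: the week-t mean of a
#' participant's outcome (on the analysis scale) is
#' \deqn{\mu_{it} = a_0 + a_1 M_{it} + \sum_k (b_{0k} + b_{1k} M_{it}) I(Z_{it}=k)
#'   + u_i + e_{it},}
#' where \eqn{M_{it}} is the realized previous-week average, \eqn{u_i} a
#' participant random intercept and \eqn{e_{it}} weekly residual noise.
#' Daily values add independent within-week noise around the weekly mean.
#'
#' @param a0 Intercept of the weekly mean on the analysis scale.
#' @param a1 Coefficient on the lagged weekly average (autoregressive
#'   persistence of the outcome).
#' @param b0 Per-category treatment intercepts, named vector over
#'   `c("activity", "sleep", "mood")` (scalar recycled).
#' @param b1 Per-category moderation slopes, same shape as `b0`.
#' @param subject_sd SD of the participant random intercept.
#' @param resid_sd SD of the weekly residual.
#' @param daily_sd SD of daily noise around the weekly mean.
#' @param outcome_scale `"raw"`: generation and analysis on the raw scale
#'   (mood). `"sqrt"`: generation on the square-root scale; daily values are
#'   squared back to the raw scale (steps, sleep).
#' @param raw_range Valid raw-scale range; daily values are clipped to it.
#' @param integer_valued Round daily raw values to integers (mood EMA).
#'
#' @return An object of class `truth_params`.
#' @export
truth_params <- function(a0, a1, b0 = 0, b1 = 0,
                         subject_sd, resid_sd, daily_sd,
                         outcome_scale = c("raw", "sqrt"),
                         raw_range = c(-Inf, Inf),
                         integer_valued = FALSE) {
  outcome_scale <- match.arg(outcome_scale)
  expand <- function(v) {
    if (length(v) == 1L && is.null(names(v))) v <- rep(v, 3L)
    if (is.null(names(v))) names(v) <- ACTIVE_ARMS
    if (!setequal(names(v), ACTIVE_ARMS)) {
      stop("treatment coefficient names must be ",
           paste(ACTIVE_ARMS, collapse = ", "), call. = FALSE)
    }
    v[ACTIVE_ARMS]
  }
  if (any(c(subject_sd, resid_sd, daily_sd) < 0)) {
    stop("all SDs must be >= 0", call. = FALSE)
  }
  structure(
    list(a0 = a0, a1 = a1, b0 = expand(b0), b1 = expand(b1),
         subject_sd = subject_sd, resid_sd = resid_sd, daily_sd = daily_sd,
         outcome_scale = outcome_scale, raw_range = raw_range,
         integer_valued = integer_valued),
    class = "truth_params")
}

#' Calibrated ground truth for the intern cohort simulation
#'
#' Default parameter sets for the three outcomes, calibrated so that the
#' simulated weekly averages at the study's cohort size reproduce the
#' trial's observed weekly summary statistics (mood mean 7.21 SD 1.43 on
#' the 1-10 EMA scale; daily steps mean 8274 SD 3285; daily sleep mean
#' 6.54 h SD 1.25 h), and with treatment/moderation coefficients set to the
#' reported moderation analysis estimates: mood moderation about -0.052 per
#' unit of previous-week mood (per-category slopes -0.050 to -0.053),
#' step moderation -0.039 on the square-root-step scale, and sleep
#' moderation -0.075 on the square-root-minute scale. Treatment intercepts
#' anchor the printed effect-curve values (e.g. a mood effect of +0.19 at
#' previous mood 3, a step effect of +165 steps at 5625 previous steps, a
#' sleep effect of +8 min at 5 h previous sleep).
#'
#' @return Named list of [truth_params()] for `mood`, `steps` (sqrt scale)
#'   and `sleep` (sqrt-minutes scale).
#' @export
ihs_truth <- function() {
  list(
    mood = truth_params(
      a0 = 3.6435, a1 = 0.5,
      b0 = c(activity = 0.31, sleep = 0.39, mood = 0.345),
      b1 = c(activity = -0.05, sleep = -0.0533333, mood = -0.0516667),
      subject_sd = 0.65, resid_sd = 0.76, daily_sd = 1.0,
      outcome_scale = "raw", raw_range = c(1, 10), integer_valued = TRUE),
    steps = truth_params(
      a0 = 52.68, a1 = 0.4,
      b0 = c(activity = 4.01705, sleep = 0, mood = 0),
      b1 = c(activity = -0.039, sleep = 0, mood = 0),
      subject_sd = 9.88, resid_sd = 6.2, daily_sd = 16,
      outcome_scale = "sqrt", raw_range = c(0, 50000)),
    sleep = truth_params(
      a0 = 11.72, a1 = 0.4,
      b0 = c(activity = 0, sleep = 1.52846, mood = 0),
      b1 = c(activity = 0, sleep = -0.075, mood = 0),
      subject_sd = 1.0, resid_sd = 0.58, daily_sd = 2.27,
      outcome_scale = "sqrt", raw_range = c(0, 1440)))
}

# Clip, and round if the measure is integer-valued (mood EMA).
clip_raw <- function(x, params) {
  if (params$integer_valued) x <- round(x)
  pmin(pmax(x, params$raw_range[1L]), params$raw_range[2L])
}

# Analysis-scale daily value from a raw daily value.
to_analysis <- function(x, params) {
  if (params$outcome_scale == "sqrt") sqrt(x) else x
}

#' Generate daily outcomes for one measure
#'
#' Simulates the outcome process week by week: the week-1 moderator is a
#' baseline (pre-study) weekly average drawn from the process's stationary
#' distribution; each subsequent week's moderator is the realized average of
#' the previous week's daily values on the analysis scale, so the lag-1
#' moderation structure of the weekly model holds by construction. Daily
#' values are the weekly mean plus daily noise, clipped to the valid raw
#' range (square-root-scale outcomes are generated on the root scale and
#' squared back).
#'
#' @param assignments Weekly arms from [randomize_weekly()].
#' @param params A [truth_params()].
#' @param seed Integer seed.
#' @param measure Column name for the raw daily values (e.g. `"mood"`).
#' @param baseline Optional fixed per-participant baseline weekly averages
#'   (analysis scale); by default drawn from the process's stationary law.
#' @return A list: `daily` (data frame `participant_id`, `study_day`,
#'   `week_index`, `<measure>` raw values), `baseline` (per-participant
#'   baseline weekly average on the analysis scale, named vector).
#' @export
generate_outcomes <- function(assignments, params, seed = 1L,
                              measure = "value", baseline = NULL) {
  stopifnot(inherits(params, "truth_params"))
  ids <- unique(assignments$participant_id)
  n <- length(ids)
  tw <- max(assignments$week)
  arm <- matrix(as.character(assignments$arm[
    order(match(assignments$participant_id, ids), assignments$week)]),
    nrow = n, ncol = tw, byrow = TRUE)

  withr_seed(seed, paste0("outcomes_", measure), {
    u <- stats::rnorm(n, 0, params$subject_sd)
    # stationary moments of the weekly-average process given u (AR(1) in the
    # weekly mean plus averaged daily noise feeding back through the lag)
    day_var <- params$daily_sd^2 / 7
    if (abs(params$a1) < 1) {
      stat_mean <- (params$a0 + u) / (1 - params$a1)
      stat_var <- (params$a1^2 * day_var + params$resid_sd^2) /
        (1 - params$a1^2) + day_var
    } else {
      # unit-root / explosive lag: no stationary law; centre the baseline
      # at the intercept-plus-subject level instead
      stat_mean <- params$a0 + u
      stat_var <- params$resid_sd^2 + day_var
    }
    if (is.null(baseline)) {
      baseline <- stat_mean + stats::rnorm(n, 0, sqrt(stat_var))
    } else {
      baseline <- rep_len(as.numeric(baseline), n)
    }
    if (params$outcome_scale == "sqrt") baseline <- pmax(baseline, 0)

    daily_raw <- matrix(NA_real_, nrow = n, ncol = 7L * tw)
    m_t <- baseline
    for (t in seq_len(tw)) {
      trt <- numeric(n)
      for (k in ACTIVE_ARMS) {
        on_k <- arm[, t] == k
        trt[on_k] <- params$b0[[k]] + params$b1[[k]] * m_t[on_k]
      }
      mu <- params$a0 + params$a1 * m_t + trt + u +
        stats::rnorm(n, 0, params$resid_sd)
      dvals <- mu + matrix(stats::rnorm(n * 7L, 0, params$daily_sd), n, 7L)
      if (params$outcome_scale == "sqrt") dvals <- pmax(dvals, 0)
      raw <- if (params$outcome_scale == "sqrt") dvals^2 else dvals
      raw <- clip_raw(raw, params)
      daily_raw[, (t - 1L) * 7L + 1:7] <- raw
      m_t <- rowMeans(to_analysis(raw, params))
    }
  })

  daily <- data.frame(
    participant_id = rep(ids, each = 7L * tw),
    study_day = rep(seq_len(7L * tw), times = n),
    week_index = rep(rep(seq_len(tw), each = 7L), times = n))
  daily[[measure]] <- as.vector(t(daily_raw))
  names(baseline) <- ids
  list(daily = daily, baseline = baseline)
}
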