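# Shared fixtures: all simulated in code, no stored data.

# Mood-like continuous outcome process (no EMA discretization) for
# estimator-property simulations.
linear_truth <- function(b0 = c(activity = 0.31, sleep = 0.39, mood = 0.345),
                         b1 = c(activity = -0.052, sleep = -0.075,
                                mood = -0.039),
                         a1 = 0.5) {
  truth_params(a0 = 3.6435, a1 = a1, b0 = b0, b1 = b1,
               subject_sd = 0.65, resid_sd = 0.76, daily_sd = 1.0,
               outcome_scale = "raw")
}

# Simulate one mood-only trial and return the weekly panel.
sim_mood_panel <- function(n, n_weeks = 26, seed = 1, truth = linear_truth()) {
  cfg <- design_config(n_participants = n, n_weeks = n_weeks, seed = seed)
  asg <- randomize_weekly(cfg)
  out <- generate_outcomes(asg, truth, seed = seed, measure = "mood")
  daily <- out$daily
  daily$arm <- asg$arm[rep(seq_len(nrow(asg)), each = 7L)]
  daily$day_of_week <- daily$study_day - (daily$week_index - 1L) * 7L
  bl <- data.frame(participant_id = unique(daily$participant_id),
                   mood = as.numeric(out$baseline))
  weekly_panel(daily, "mood", baseline = bl)
}

# One simulate-aggregate-fit replicate; returns the fit.
sim_mood_fit <- function(n, n_weeks = 26, seed = 1, truth = linear_truth(),
                         mode = "multi") {
  panel <- sim_mood_panel(n, n_weeks, seed, truth)
  fit_wcls(build_design_matrix(panel, mode = mode))
}

# Minimal fit-shaped object for effect-curve arithmetic with known
# coefficients (zero covariance unless given).
make_fit <- function(b0, b1, category = "mood", transform = "none",
                     vcov2 = matrix(0, 2, 2)) {
  nm <- c(paste0("trt_", category), paste0("trt_", category, ":moderator"))
  vc <- matrix(0, 2, 2, dimnames = list(nm, nm))
  vc[] <- vcov2
  structure(list(coefficients = stats::setNames(c(b0, b1), nm),
                 vcov = vc, mode = "multi", transform = transform,
                 n_clusters = 2L, n_obs = 2L),
            class = "wcls_fit")
}
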