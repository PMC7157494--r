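#' Column name of a measure in the daily panel
#' @keywords internal
measure_column <- function(measure) {
  switch(measure, mood = "mood", steps = "steps", sleep = "sleep_minutes",
         stop("unknown measure: ", measure, call. = FALSE))
}

#' Analysis-scale transform of a measure
#' @keywords internal
measure_transform <- function(measure) {
  if (measure %in% c("steps", "sleep")) "sqrt" else "none"
}

#' Simulate a complete micro-randomized trial
#'
#' Chains the design and outcome generators: weekly arm randomization,
#' daily Bernoulli delivery, alternating without-replacement message draws,
#' daily mood / step / sleep outcomes under the weekly moderation model,
#' and (optionally) missing-at-random attrition.
#'
#' @param config A [design_config()].
#' @param truth Named list of [truth_params()] for mood, steps, sleep
#'   (default [ihs_truth()]).
#' @param missingness `NULL` for a complete panel, or a named list of
#'   [missingness_spec()] (default pattern via [ihs_missingness()]).
#' @return A list of class `mrt_sim`: `daily` (the participant-day panel:
#'   `participant_id`, `study_day`, `week_index`, `day_of_week`, `arm`,
#'   `delivered`, `message_id`, `mood`, `steps`, `sleep_minutes`),
#'   `baseline` (data frame of analysis-scale baseline weekly averages),
#'   `assignments`, `config`, `truth`.
#' @export
simulate_trial <- function(config, truth = ihs_truth(), missingness = NULL) {
  assignments <- randomize_weekly(config)
  daily <- schedule_daily(assignments, config$daily_prob, seed = config$seed)
  daily <- draw_messages(daily, config$bucket_sizes, seed = config$seed)

  baselines <- list()
  for (m in names(truth)) {
    out <- generate_outcomes(assignments, truth[[m]], seed = config$seed,
                             measure = measure_column(m))
    stopifnot(nrow(out$daily) == nrow(daily))
    daily[[measure_column(m)]] <- out$daily[[measure_column(m)]]
    baselines[[m]] <- out$baseline
  }

  if (!is.null(missingness)) {
    cols <- vapply(names(missingness), measure_column, "")
    spec <- stats::setNames(missingness, cols)
    base_cols <- stats::setNames(baselines[names(missingness)], cols)
    daily <- impose_missingness(
      daily, spec, measures = cols, baselines = base_cols,
      sqrt_measures = c("steps", "sleep_minutes"), seed = config$seed)
  }

  base_df <- data.frame(participant_id = unique(daily$participant_id))
  for (m in names(baselines)) base_df[[m]] <- as.numeric(baselines[[m]])
  structure(list(daily = daily, baseline = base_df,
                 assignments = assignments, config = config, truth = truth),
            class = "mrt_sim")
}

#' @export
print.mrt_sim <- function(x, ...) {
  cat("Simulated micro-randomized trial:",
      x$config$n_participants, "participants x",
      x$config$n_weeks, "weeks (", nrow(x$daily), "participant-days )\n")
  invisible(x)
}
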