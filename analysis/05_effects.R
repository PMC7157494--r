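#!/usr/bin/env Rscript
# Stage 5: turn fitted coefficients into the reportables.
#
# Effect-versus-moderator curves per aim; square-root-scale effects
# retransformed to natural units (steps, minutes of sleep) by anchoring the
# control mean at the moderator's own value; standardized effect sizes
# using the cohort SDs of the weekly-average outcomes; tables and
# histogram-annotated figures under results/.

suppressPackageStartupMessages(library(mrtmod))

read_fit <- function(path) {
  j <- jsonlite::read_json(path)
  nm <- names(j$coefficients)
  se <- unlist(j$se)
  structure(list(coefficients = unlist(j$coefficients),
                 vcov = diag(se^2, length(se)) |>
                   (\(m) {dimnames(m) <- list(nm, nm); m})(),
                 mode = j$mode, transform = j$transform,
                 n_clusters = j$n_clusters, n_obs = j$n_obs),
            class = "wcls_fit")
}
# NB: the JSON keeps only marginal SEs, so the CI bands below ignore the
# b0-b1 covariance; the point curves are exact.

sds <- list(mood = 1.43, steps = 3285, sleep = 75)  # cohort weekly-avg SDs

## primary aim: pooled notification effect on mood vs previous mood
fit_mood <- read_fit("results/pooled_mood_binary.json")
grid_mood <- 3:9
cur_mood <- effect_curve(fit_mood, "binary", grid_mood,
                         outcome_sd = sds$mood)
panel_mood <- read_weekly_panel("results/weekly_mood.csv",
                                measure = "mood", transform = "none")
render_report(cur_mood, panel_mood, "results/effects_mood.csv",
              "results/fig_mood_moderation.png")
cat("mood effect at previous mood 3 and 9:",
    sprintf("%+.2f", cur_mood$effect[grid_mood == 3]),
    sprintf("%+.2f", cur_mood$effect[grid_mood == 9]),
    sprintf("(crossing at %.1f)", attr(cur_mood, "crossing")), "\n")

## exploratory subaim: per-category curves on mood
fit_mood_multi <- read_fit("results/fit_mood_multi.json")
cur_expl <- exploratory_curves(fit_mood_multi, grid_mood,
                               binary_fit = fit_mood)
render_report(cur_expl, panel_mood, "results/effects_mood_categories.csv",
              "results/fig_mood_categories.png")

## secondary aim 1: activity notifications on steps vs previous steps
fit_steps <- read_fit("results/pooled_steps_multi.json")
grid_steps <- seq(3000, 16000, by = 250)
cur_steps <- effect_curve(fit_steps, "activity", grid_steps,
                          outcome_sd = sds$steps)
panel_steps <- read_weekly_panel("results/weekly_steps.csv",
                                 measure = "steps", transform = "sqrt")
render_report(cur_steps, panel_steps, "results/effects_steps.csv",
              "results/fig_steps_moderation.png")
lo <- which.min(abs(grid_steps - 5625)); hi <- which.min(abs(grid_steps - 12100))
cat(sprintf("step effect: %+d steps at prev 5625 (size %.2f); %+d at prev 12100 (size %.2f)\n",
            round(cur_steps$effect_natural[lo]), cur_steps$effect_size[lo],
            round(cur_steps$effect_natural[hi]), cur_steps$effect_size[hi]))

## secondary aim 2: sleep notifications on sleep vs previous sleep
fit_sleep <- read_fit("results/pooled_sleep_multi.json")
grid_sleep <- seq(240, 600, by = 10)          # minutes: 4 h to 10 h
cur_sleep <- effect_curve(fit_sleep, "sleep", grid_sleep,
                          outcome_sd = sds$sleep)
panel_sleep <- read_weekly_panel("results/weekly_sleep.csv",
                                 measure = "sleep", transform = "sqrt")
render_report(cur_sleep, panel_sleep, "results/effects_sleep.csv",
              "results/fig_sleep_moderation.png")
lo <- which.min(abs(grid_sleep - 300)); hi <- which.min(abs(grid_sleep - 480))
cat(sprintf("sleep effect: %+d min at prev 5 h (size %.2f); %+d min at prev 8 h (size %.2f)\n",
            round(cur_sleep$effect_natural[lo]), cur_sleep$effect_size[lo],
            round(cur_sleep$effect_natural[hi]), cur_sleep$effect_size[hi]))
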