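#!/usr/bin/env Rscript
# Stage 2: aggregate the daily panel to the weekly analysis unit.
#
# Weekly outcomes are 7-day averages of the daily measure on its analysis
# scale (raw mood; square root of steps and of sleep minutes, transformed
# daily BEFORE averaging). Each week carries the previous week's averages
# of all three measures (the moderator and lagged controls); week 1 uses
# the pre-study baseline. Writes one weekly panel CSV per outcome.

suppressPackageStartupMessages(library(mrtmod))

daily <- read_daily_panel("results/daily_panel.csv")
baseline <- utils::read.csv("results/baseline.csv")

for (measure in c("mood", "steps", "sleep")) {
  panel <- weekly_panel(daily, measure, baseline = baseline)
  path <- sprintf("results/weekly_%s.csv", measure)
  write_weekly_panel(panel, path)
  n_cc <- sum(stats::complete.cases(panel[, c("y", "moderator")]))
  cat(sprintf("%-6s panel: %d participant-weeks, %d complete on (y, moderator); wrote %s\n",
              measure, nrow(panel), n_cc, path))
}
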