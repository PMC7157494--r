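#' Notification categories used throughout the package
#'
#' Weekly randomization assigns one of four arms: three active notification
#' categories ("activity", "sleep", "mood") and a no-notification control
#' ("none"). "none" is the reference category in all analyses; the
#' multicategorical coefficient dimensions are ordered activity, sleep, mood.
#'
#' @format Character vector of length 4.
#' @export
ARM_LEVELS <- c("activity", "sleep", "mood", "none")

#' Active (non-control) notification categories
#' @rdname ARM_LEVELS
#' @export
ACTIVE_ARMS <- c("activity", "sleep", "mood")

#' Trial design configuration
#'
#' Bundles the randomization design of a weekly micro-randomized trial:
#' cohort size, number of weekly decision points, the per-arm randomization
#' probabilities, the daily within-week delivery probability, and the size
#' of the (category, type) message buckets.
#'
#' @param n_participants Number of participants.
#' @param n_weeks Number of weekly decision points (default 26, i.e. six
#'   months). At least 2, because the moderator is the previous week's
#'   average.
#' @param arm_probs Named numeric vector of randomization probabilities over
#'   `c("activity", "sleep", "mood", "none")`; must sum to 1. Default
#'   uniform (1/4 each).
#' @param daily_prob Probability that a notification is delivered on any
#'   given day of an active week (default 0.5, giving 3.5 expected
#'   deliveries per active week).
#' @param bucket_sizes Number of distinct messages per (category, type)
#'   bucket (default 7).
#' @param assignment_mode `"independent"` draws each week's arm i.i.d. from
#'   `arm_probs`; `"block"` permutes the four categories within consecutive
#'   4-week blocks (randomization without replacement).
#' @param seed Integer seed recorded in the configuration; all simulation
#'   functions that take a config derive their random streams from it.
#'
#' @return An object of class `design_config`.
#' @export
design_config <- function(n_participants,
                          n_weeks = 26L,
                          arm_probs = c(activity = 0.25, sleep = 0.25,
                                        mood = 0.25, none = 0.25),
                          daily_prob = 0.5,
                          bucket_sizes = 7L,
                          assignment_mode = c("independent", "block"),
                          seed = 1L) {
  assignment_mode <- match.arg(assignment_mode)
  n_participants <- as.integer(n_participants)
  n_weeks <- as.integer(n_weeks)
  if (n_participants < 1L) stop("`n_participants` must be >= 1", call. = FALSE)
  if (n_weeks < 2L) {
    stop("`n_weeks` must be >= 2 (the moderator is the previous week's average)",
         call. = FALSE)
  }
  arm_probs <- check_arm_probs(arm_probs)
  if (!is.numeric(daily_prob) || length(daily_prob) != 1L ||
      daily_prob < 0 || daily_prob > 1) {
    stop("`daily_prob` must be a single probability in [0, 1]", call. = FALSE)
  }
  if (bucket_sizes < 1L) stop("`bucket_sizes` must be >= 1", call. = FALSE)
  structure(
    list(n_participants = n_participants,
         n_weeks = n_weeks,
         arm_probs = arm_probs,
         daily_prob = daily_prob,
         bucket_sizes = as.integer(bucket_sizes),
         assignment_mode = assignment_mode,
         seed = as.integer(seed)),
    class = "design_config")
}

# Validate and order arm probabilities; tolerance on the sum is 1e-12.
check_arm_probs <- function(arm_probs) {
  if (is.null(names(arm_probs))) {
    if (length(arm_probs) != 4L) {
      stop("`arm_probs` must have one entry per arm (activity, sleep, mood, none)",
           call. = FALSE)
    }
    names(arm_probs) <- ARM_LEVELS
  }
  if (!setequal(names(arm_probs), ARM_LEVELS)) {
    stop("`arm_probs` names must be ", paste(ARM_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  arm_probs <- arm_probs[ARM_LEVELS]
  if (any(arm_probs < 0) || any(arm_probs > 1)) {
    stop("`arm_probs` entries must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(arm_probs) - 1) > 1e-12) {
    stop("`arm_probs` must sum to 1 (got ", format(sum(arm_probs), digits = 15),
         ")", call. = FALSE)
  }
  arm_probs
}

#' @export
print.design_config <- function(x, ...) {
  cat("Micro-randomized trial design\n")
  cat("  participants:", x$n_participants, " weeks:", x$n_weeks, "\n")
  cat("  arm probabilities:",
      paste(sprintf("%s=%.3g", names(x$arm_probs), x$arm_probs), collapse = " "),
      "\n")
  cat("  daily delivery probability:", x$daily_prob,
      " assignment:", x$assignment_mode, "\n")
  invisible(x)
}

#' Weekly arm randomization
#'
#' Assigns each participant-week to one of the four arms. In
#' `"independent"` mode each week is an i.i.d. draw from the arm
#' probabilities; in `"block"` mode the four categories are permuted within
#' consecutive 4-week blocks, so every participant receives each category
#' exactly once per block (randomization without replacement).
#'
#' @param config A [design_config()].
#' @return A data frame with columns `participant_id`, `week`, `arm`
#'   (factor with levels activity, sleep, mood, none), one row per
#'   participant-week, ordered by participant then week.
#' @export
randomize_weekly <- function(config) {
  stopifnot(inherits(config, "design_config"))
  n <- config$n_participants
  tw <- config$n_weeks
  withr_seed(config$seed, "randomize", {
    if (config$assignment_mode == "independent") {
      arm <- sample(ARM_LEVELS, n * tw, replace = TRUE, prob = config$arm_probs)
    } else {
      n_blocks <- ceiling(tw / 4L)
      arm <- character(n * tw)
      idx <- 0L
      for (i in seq_len(n)) {
        seq_i <- unlist(lapply(seq_len(n_blocks),
                               function(b) sample(ARM_LEVELS, 4L)))
        arm[idx + seq_len(tw)] <- seq_i[seq_len(tw)]
        idx <- idx + tw
      }
    }
  })
  data.frame(
    participant_id = rep(seq_len(n), each = tw),
    week = rep(seq_len(tw), times = n),
    arm = factor(arm, levels = ARM_LEVELS))
}

#' Daily delivery schedule
#'
#' Expands weekly arm assignments to a daily schedule: within an active week
#' each of the 7 days independently receives a notification with probability
#' `daily_prob`; control ("none") weeks never deliver.
#'
#' @param assignments Output of [randomize_weekly()].
#' @param daily_prob Daily delivery probability in an active week.
#' @param seed Integer seed.
#' @return A data frame with one row per participant-day: `participant_id`,
#'   `study_day` (1-based), `week_index`, `day_of_week` (1..7), `arm`,
#'   `delivered` (logical).
#' @export
schedule_daily <- function(assignments, daily_prob = 0.5, seed = 1L) {
  if (!is.numeric(daily_prob) || daily_prob < 0 || daily_prob > 1) {
    stop("`daily_prob` must lie in [0, 1]", call. = FALSE)
  }
  nr <- nrow(assignments)
  daily <- assignments[rep(seq_len(nr), each = 7L), ]
  rownames(daily) <- NULL
  names(daily)[names(daily) == "week"] <- "week_index"
  daily$day_of_week <- rep(1:7, times = nr)
  daily$study_day <- (daily$week_index - 1L) * 7L + daily$day_of_week
  active <- daily$arm != "none"
  withr_seed(seed, "schedule", {
    delivered <- logical(nrow(daily))
    delivered[active] <- stats::runif(sum(active)) < daily_prob
  })
  daily$delivered <- delivered
  daily[, c("participant_id", "study_day", "week_index", "day_of_week",
            "arm", "delivered")]
}

# Run `code` under a deterministic RNG stream derived from (seed, label),
# restoring the caller's RNG state afterwards. Streams for different labels
# are decoupled so that e.g. regenerating outcomes does not shift the
# randomization. The derived seed stays within 32-bit integer range.
withr_seed <- function(seed, label, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  offset <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  set.seed((as.integer(seed) %% 1000003L) * 2011L + offset %% 100003L)
  force(code)
}
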