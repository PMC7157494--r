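#' Build the weekly analysis panel from a daily panel
#'
#' Aggregates daily observations to the weekly analysis unit. The daily
#' transform (identity for mood, square root for steps and sleep) is
#' applied to each daily value *before* averaging, so the weekly outcome is
#' the average daily square-root count, not the square root of the average.
#' Each week carries the previous week's averages of all measures present
#' (the moderator and lagged control variables); week 1 uses the baseline
#' (pre-study) averages when supplied.
#'
#' @param daily Daily panel with columns `participant_id`, `week_index`,
#'   `arm` and the measure columns (`mood`, `steps`, `sleep_minutes`, any
#'   subset). Missing daily values are `NA`; weekly averages use the
#'   observed days only, and a week with no observed days has `NA` outcome.
#' @param measure Which measure is the outcome: `"mood"`, `"steps"` or
#'   `"sleep"`.
#' @param transform `"none"` or `"sqrt"`; defaults to the measure's
#'   conventional analysis scale ([measure_transform()]).
#' @param baseline Optional data frame `participant_id` plus analysis-scale
#'   baseline averages named by measure (as from [simulate_trial()]).
#' @return A `week_record` data frame: `participant_id`, `week`, `arm`,
#'   `y`, `n_days` (observed days), `moderator` (previous week's average of
#'   the outcome measure), `baseline_y`, and `lag_<measure>` columns for
#'   every measure present.
#' @export
weekly_panel <- function(daily, measure = c("mood", "steps", "sleep"),
                         transform = NULL, baseline = NULL) {
  measure <- match.arg(measure)
  if (is.null(transform)) transform <- measure_transform(measure)
  transform <- match.arg(transform, c("none", "sqrt"))

  ids <- unique(daily$participant_id)
  n <- length(ids)
  tw <- max(daily$week_index)
  pid <- match(daily$participant_id, ids)
  cell <- (pid - 1L) * tw + daily$week_index

  present <- intersect(c("mood", "steps", "sleep"),
                       c("mood", "steps", "sleep")[
                         c("mood", "steps", "sleep_minutes") %in% names(daily)])

  avg_of <- function(m) {
    vals <- daily[[measure_column(m)]]
    if (measure_transform(m) == "sqrt") {
      if (any(vals < 0, na.rm = TRUE)) {
        stop("negative daily ", m, " value under sqrt transform", call. = FALSE)
      }
      vals <- sqrt(vals)
    }
    ok <- !is.na(vals)
    s <- numeric(n * tw)
    cnt <- numeric(n * tw)
    s[sort(unique(cell[ok]))] <- rowsum(vals[ok], cell[ok])[, 1L]
    cnt[sort(unique(cell[ok]))] <- rowsum(rep(1, sum(ok)), cell[ok])[, 1L]
    avg <- ifelse(cnt > 0, s / pmax(cnt, 1), NA_real_)
    list(avg = matrix(avg, n, tw, byrow = TRUE),
         n_obs = matrix(cnt, n, tw, byrow = TRUE))
  }

  # the outcome's transform may differ from the measure's convention
  out_vals <- daily[[measure_column(measure)]]
  if (transform == "sqrt") {
    if (any(out_vals < 0, na.rm = TRUE)) {
      stop("negative daily value under sqrt transform", call. = FALSE)
    }
    out_vals <- sqrt(out_vals)
  }
  ok <- !is.na(out_vals)
  s <- numeric(n * tw); cnt <- numeric(n * tw)
  s[sort(unique(cell[ok]))] <- rowsum(out_vals[ok], cell[ok])[, 1L]
  cnt[sort(unique(cell[ok]))] <- rowsum(rep(1, sum(ok)), cell[ok])[, 1L]
  y_mat <- matrix(ifelse(cnt > 0, s / pmax(cnt, 1), NA_real_), n, tw,
                  byrow = TRUE)
  n_mat <- matrix(cnt, n, tw, byrow = TRUE)

  lag_mats <- lapply(stats::setNames(present, present), function(m) {
    a <- avg_of(m)$avg
    lagm <- cbind(NA_real_, a[, -tw, drop = FALSE])
    if (!is.null(baseline) && m %in% names(baseline)) {
      lagm[, 1L] <- baseline[[m]][match(ids, baseline$participant_id)]
    }
    # weeks with no observed days pass the last available average forward
    for (t in seq_len(tw)[-1L]) {
      nas <- is.na(lagm[, t]) & !is.na(lagm[, t - 1L])
      lagm[nas, t] <- lagm[nas, t - 1L]
    }
    lagm
  })

  arm_mat <- matrix(as.character(daily$arm)[daily$day_of_week == 1L],
                    n, tw, byrow = TRUE)
  panel <- data.frame(
    participant_id = rep(ids, each = tw),
    week = rep(seq_len(tw), times = n),
    arm = factor(as.vector(t(arm_mat)), levels = ARM_LEVELS),
    y = as.vector(t(y_mat)),
    n_days = as.integer(as.vector(t(n_mat))))
  panel$moderator <- as.vector(t(lag_mats[[measure]]))
  if (!is.null(baseline) && measure %in% names(baseline)) {
    panel$baseline_y <-
      rep(baseline[[measure]][match(ids, baseline$participant_id)], each = tw)
  }
  for (m in present) panel[[paste0("lag_", m)]] <- as.vector(t(lag_mats[[m]]))
  attr(panel, "measure") <- measure
  attr(panel, "transform") <- transform
  class(panel) <- c("week_record", "data.frame")
  panel
}

#' Build the centered design matrix for the WCLS fit
#'
#' Treatment indicators are centered at the known randomization
#' probabilities: for each non-reference category \eqn{k}, the column is
#' \eqn{\tilde Z_{tk} = I(Z_t = k) - p_k}, together with its interaction
#' with the moderator. In `"binary"` mode the three active categories
#' collapse into a single indicator centered at their total probability.
#' Because centering uses the true randomization probabilities, the
#' observation weights default to 1.
#'
#' @param panel A [weekly_panel()] (complete; rows with missing outcome,
#'   moderator or controls are dropped and counted).
#' @param arm_probs Randomization probabilities (named over the four arms).
#' @param mode `"multi"` (per-category coefficients) or `"binary"`.
#' @param moderator Name of the moderator column.
#' @param controls Control columns; default is the baseline outcome average
#'   plus all lagged-measure columns other than the moderator itself.
#' @param weights Optional observation weights (default 1).
#' @return Object of class `wcls_design`: response `y`, matrix `X`,
#'   `cluster`, `weights`, plus metadata used by [fit_wcls()].
#' @export
build_design_matrix <- function(panel,
                                arm_probs = c(activity = 0.25, sleep = 0.25,
                                              mood = 0.25, none = 0.25),
                                mode = c("multi", "binary"),
                                moderator = "moderator",
                                controls = NULL,
                                weights = NULL) {
  mode <- match.arg(mode)
  arm_probs <- check_arm_probs(arm_probs)
  if (!all(as.character(panel$arm) %in% ARM_LEVELS)) {
    stop("unknown arm label in panel", call. = FALSE)
  }
  if (is.null(controls)) {
    lag_cols <- grep("^lag_", names(panel), value = TRUE)
    own <- attr(panel, "measure")
    lag_cols <- setdiff(lag_cols, paste0("lag_", own %||% ""))
    controls <- intersect(c("baseline_y", lag_cols), names(panel))
  }
  need <- c("y", moderator, controls)
  keep <- stats::complete.cases(panel[, need, drop = FALSE])
  dropped <- sum(!keep)
  dat <- panel[keep, , drop = FALSE]

  m <- dat[[moderator]]
  X <- cbind(1, as.matrix(dat[, controls, drop = FALSE]), m)
  colnames(X) <- c("(Intercept)", controls, "moderator")

  if (mode == "multi") {
    treat_cols <- paste0("trt_", ACTIVE_ARMS)
    for (k in ACTIVE_ARMS) {
      zc <- as.numeric(dat$arm == k) - arm_probs[[k]]
      X <- cbind(X, zc)
      colnames(X)[ncol(X)] <- paste0("trt_", k)
    }
    for (k in ACTIVE_ARMS) {
      zc <- as.numeric(dat$arm == k) - arm_probs[[k]]
      X <- cbind(X, zc * m)
      colnames(X)[ncol(X)] <- paste0("trt_", k, ":moderator")
    }
    inter_cols <- paste0("trt_", ACTIVE_ARMS, ":moderator")
  } else {
    p_active <- sum(arm_probs[ACTIVE_ARMS])
    zc <- as.numeric(dat$arm != "none") - p_active
    X <- cbind(X, trt = zc, `trt:moderator` = zc * m)
    treat_cols <- "trt"
    inter_cols <- "trt:moderator"
  }

  w <- if (is.null(weights)) rep(1, nrow(dat)) else weights[keep]
  structure(
    list(y = dat$y, X = X, cluster = dat$participant_id, weights = w,
         arm_probs = arm_probs, mode = mode, moderator = moderator,
         controls = controls, treat_cols = treat_cols,
         inter_cols = inter_cols, n_dropped = dropped,
         measure = attr(panel, "measure"),
         transform = attr(panel, "transform")),
    class = "wcls_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
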