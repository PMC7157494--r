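#' Moderated treatment-effect curve
#'
#' The analysis-scale effect of a week of category-k notifications versus a
#' no-notification week, as a function of the moderator:
#' \eqn{\delta(m) = b_{0k} + b_{1k} g(m)}, where \eqn{g} is the analysis
#' transform (identity for mood, square root for steps/sleep) and the grid
#' is given in natural units. For square-root outcomes the curve is also
#' retransformed to natural units via [retransform_sqrt()]. Pointwise 95%
#' bands use the delta method with the coefficients' joint sandwich
#' covariance.
#'
#' @param fit A [fit_wcls()] (or pooled) result.
#' @param category Notification category, or `"binary"` for a binary-mode
#'   fit's pooled indicator.
#' @param grid Moderator values in natural units.
#' @param outcome_sd Optional SD of the weekly-average outcome in natural
#'   units; when given, standardized effect sizes are attached.
#' @param grid_range Plausible natural-unit moderator range; grid values
#'   outside it trigger a warning (extrapolation), not an error.
#' @return An `effect_curve` data frame: `category`, `moderator` (natural
#'   units), `moderator_analysis`, `effect` (analysis scale), `se`,
#'   `ci_lower`, `ci_upper`, and for sqrt outcomes `effect_natural` (plus
#'   `effect_size` when `outcome_sd` is given). The attribute `"crossing"`
#'   holds the natural-unit moderator value where the effect changes sign.
#' @export
effect_curve <- function(fit, category, grid, outcome_sd = NULL,
                         grid_range = NULL) {
  mc <- moderation_coef(fit, category)
  transform <- fit$transform %||% "none"
  if (!is.null(grid_range) &&
      (any(grid < grid_range[1L]) || any(grid > grid_range[2L]))) {
    warning("grid extends outside the plausible moderator range; ",
            "effects there are extrapolations", call. = FALSE)
  }
  g <- if (transform == "sqrt") sqrt(grid) else grid
  delta <- mc$b0 + mc$b1 * g
  se <- sqrt(pmax(mc$vcov[1, 1] + g^2 * mc$vcov[2, 2] +
                    2 * g * mc$vcov[1, 2], 0))
  out <- data.frame(category = category, moderator = grid,
                    moderator_analysis = g, effect = delta, se = se,
                    ci_lower = delta - 1.96 * se,
                    ci_upper = delta + 1.96 * se)
  if (transform == "sqrt") {
    out$effect_natural <- retransform_sqrt(delta, grid)
    out$ci_lower_natural <- retransform_sqrt(out$ci_lower, grid)
    out$ci_upper_natural <- retransform_sqrt(out$ci_upper, grid)
    if (!is.null(outcome_sd)) {
      out$effect_size <- standardized_effect(out$effect_natural, outcome_sd)
    }
  } else if (!is.null(outcome_sd)) {
    out$effect_size <- standardized_effect(out$effect, outcome_sd)
  }
  crossing <- if (mc$b1 != 0) {
    root <- -mc$b0 / mc$b1
    if (transform == "sqrt") {
      if (root >= 0) root^2 else NA_real_
    } else root
  } else NA_real_
  attr(out, "crossing") <- crossing
  attr(out, "transform") <- transform
  class(out) <- c("effect_curve", "data.frame")
  out
}

#' Retransform a square-root-scale effect to natural units
#'
#' Anchors the control-condition mean on the analysis scale at
#' \eqn{\sqrt m} (the moderator's own value), so the treated mean is
#' \eqn{\sqrt m + \delta} and the natural-scale effect is
#' \deqn{(\sqrt m + \delta)^2 - m.}
#'
#' @param delta Analysis-scale (square-root) effect(s).
#' @param m Moderator value(s) in natural units (must be >= 0).
#' @return Natural-scale effect(s).
#' @seealso [calibrate_sqrt_delta()] for the inverse.
#' @export
retransform_sqrt <- function(delta, m) {
  if (any(m < 0)) stop("moderator values must be >= 0", call. = FALSE)
  (sqrt(m) + delta)^2 - m
}

#' Analysis-scale effect that yields a given natural-scale effect
#'
#' Inverse of [retransform_sqrt()]: solves \eqn{(\sqrt m + \delta)^2 - m =
#' e} for \eqn{\delta}, i.e. \eqn{\delta = \sqrt{m + e} - \sqrt m}. Used to
#' anchor effect-curve intercepts at a known natural-scale effect.
#'
#' @param effect Natural-scale effect `e` (must satisfy `m + e >= 0`).
#' @param m Moderator value in natural units.
#' @return Analysis-scale effect \eqn{\delta}.
#' @export
calibrate_sqrt_delta <- function(effect, m) {
  if (any(m < 0)) stop("moderator values must be >= 0", call. = FALSE)
  if (any(m + effect < 0)) {
    stop("`m + effect` must be >= 0 on the raw scale", call. = FALSE)
  }
  sqrt(m + effect) - sqrt(m)
}

#' Standardized effect size
#'
#' Effect divided by the SD of the weekly-average outcome (both in natural
#' units), rounded for reporting.
#'
#' @param effect Natural-scale effect(s).
#' @param sd SD of the weekly-average outcome (> 0).
#' @param digits Reporting precision (default 2 decimals).
#' @return Rounded effect-size ratio(s).
#' @export
standardized_effect <- function(effect, sd, digits = 2) {
  if (!is.numeric(sd) || any(sd <= 0)) stop("`sd` must be > 0", call. = FALSE)
  round(effect / sd, digits)
}

#' Per-category effect curves for a multicategorical fit
#'
#' One curve per notification category, optionally with the pooled
#' binary-treatment line (from a companion binary-mode fit) for reference.
#'
#' @param fit Multicategorical [fit_wcls()] result.
#' @param grid Moderator grid in natural units.
#' @param binary_fit Optional binary-mode fit for the pooled line.
#' @param outcome_sd Optional natural-unit outcome SD.
#' @return A single `effect_curve` data frame stacking the categories
#'   (`category` column distinguishes them; the pooled line is
#'   `"pooled"`).
#' @export
exploratory_curves <- function(fit, grid, binary_fit = NULL,
                               outcome_sd = NULL) {
  if (fit$mode != "multi") {
    stop("`fit` must use multicategorical treatment coding", call. = FALSE)
  }
  curves <- lapply(ACTIVE_ARMS, function(k)
    effect_curve(fit, k, grid, outcome_sd = outcome_sd))
  if (!is.null(binary_fit)) {
    pooled <- effect_curve(binary_fit, "binary", grid,
                           outcome_sd = outcome_sd)
    pooled$category <- "pooled"
    curves <- c(curves, list(pooled))
  }
  out <- do.call(rbind, lapply(curves, as.data.frame))
  class(out) <- c("effect_curve", "data.frame")
  out
}

#' Write an effect-curve report: table plus annotated figure
#'
#' Writes a per-category effect table (grid value, effect, CI) as CSV and a
#' figure of the effect curves over a scaled histogram of the observed
#' moderator values. Output is deterministic for fixed inputs.
#'
#' @param curves An `effect_curve` data frame (possibly several categories).
#' @param panel The weekly panel whose `moderator` column supplies the
#'   histogram (natural units are reconstructed for sqrt outcomes).
#' @param table_path CSV output path.
#' @param figure_path Figure output path (`.png` or `.svg`); `NULL` skips
#'   the figure.
#' @param natural_scale Plot natural-scale effects when available.
#' @param bins Histogram bin count.
#' @return Invisibly, the plotted ggplot object.
#' @export
render_report <- function(curves, panel, table_path, figure_path = NULL,
                          natural_scale = TRUE, bins = 30) {
  if (nrow(panel) == 0L) stop("empty weekly panel", call. = FALSE)
  tab <- as.data.frame(curves)
  eff_col <- if (natural_scale && "effect_natural" %in% names(tab)) {
    c("effect_natural", "ci_lower_natural", "ci_upper_natural")
  } else c("effect", "ci_lower", "ci_upper")
  out_tab <- tab[, c("category", "moderator", eff_col)]
  names(out_tab) <- c("category", "moderator", "effect", "ci_lower",
                      "ci_upper")
  utils::write.csv(out_tab, table_path, row.names = FALSE)

  mod_vals <- panel$moderator[!is.na(panel$moderator)]
  if (identical(attr(curves, "transform"), "sqrt")) mod_vals <- mod_vals^2
  h <- graphics::hist(mod_vals, breaks = bins, plot = FALSE)
  ymax <- max(abs(c(out_tab$ci_lower, out_tab$ci_upper, out_tab$effect)))
  hist_df <- data.frame(mid = h$mids,
                        top = -ymax + h$counts / max(h$counts) * 0.4 * ymax)
  p <- ggplot2::ggplot(out_tab,
                       ggplot2::aes(x = moderator, y = effect,
                                    colour = category)) +
    ggplot2::geom_rect(data = hist_df, inherit.aes = FALSE,
                       ggplot2::aes(xmin = mid - diff(h$mids[1:2]) / 2,
                                    xmax = mid + diff(h$mids[1:2]) / 2,
                                    ymin = -ymax, ymax = top),
                       fill = "grey80") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_lower,
                                      ymax = ci_upper,
                                      fill = category),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "previous week's average (moderator)",
                  y = "estimated treatment effect vs no notifications") +
    ggplot2::theme_minimal()
  if (!is.null(figure_path)) {
    ggplot2::ggsave(figure_path, p, width = 7, height = 4.5, dpi = 150)
  }
  invisible(p)
}
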