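#' Multiply impute missing daily values
#'
#' Daily-level stochastic regression imputation honouring the longitudinal
#' and sequentially-randomized structure of the trial. For each measure, a
#' normal linear model on the analysis scale is fitted to the observed days
#' with predictors: the previous week's (completed) average of the measure,
#' the participant's baseline average, the week index, day-of-week dummies,
#' and the current week's arm dummies. For each of the M imputations, new
#' regression parameters are drawn from their approximate posterior
#' (sigma^2 from the scaled inverse chi-square, coefficients from their
#' normal), and missing days are filled sequentially week by week with
#' stochastic draws - never conditional means - so that imputed week t
#' feeds the week t+1 predictor. Imputed values are clipped to the valid
#' range (and rounded for the integer mood scale).
#'
#' @param daily Daily panel with `NA`s in the measure columns.
#' @param M Number of imputations (>= 1; >= 2 for pooling).
#' @param baseline Optional baseline data frame (analysis scale, columns
#'   named by measure). Participants without baseline fall back to their
#'   observed running mean, then to the cohort model intercept.
#' @param measures Measures to impute.
#' @param seed Integer seed; the M imputations use independent substreams.
#' @return List of M completed daily tables.
#' @export
impute_daily <- function(daily, M = 20L, baseline = NULL,
                         measures = c("mood", "steps", "sleep"),
                         seed = 1L) {
  M <- as.integer(M)
  if (M < 1L) stop("`M` must be >= 1", call. = FALSE)
  measures <- intersect(measures,
                        c("mood", "steps", "sleep")[
                          c("mood", "steps", "sleep_minutes") %in% names(daily)])

  ids <- unique(daily$participant_id)
  n <- length(ids)
  tw <- max(daily$week_index)
  pid <- match(daily$participant_id, ids)
  week <- daily$week_index
  dow <- daily$day_of_week
  arm <- as.character(daily$arm)

  # analysis-scale values, clip specs, per-measure model prep
  prep <- list()
  for (m in measures) {
    col <- measure_column(m)
    vals <- daily[[col]]
    sqrt_scale <- measure_transform(m) == "sqrt"
    av <- if (sqrt_scale) sqrt(vals) else vals
    miss <- is.na(av)
    if (!any(miss)) {
      prep[[m]] <- list(none_missing = TRUE)
      next
    }
    base <- if (!is.null(baseline) && m %in% names(baseline)) {
      baseline[[m]][match(ids, baseline$participant_id)]
    } else rep(NA_real_, n)
    run_mean <- tapply(av, pid, mean, na.rm = TRUE)[as.character(seq_len(n))]
    base[is.na(base)] <- run_mean[is.na(base)]
    base[is.na(base)] <- mean(av, na.rm = TRUE)

    # observed previous-week averages (carry last available forward)
    ok <- which(!miss)
    cell <- (pid - 1L) * tw + week
    obs_sum <- numeric(n * tw)
    obs_cnt <- numeric(n * tw)
    idx <- sort(unique(cell[ok]))
    obs_sum[idx] <- rowsum(av[ok], cell[ok])[, 1L]
    obs_cnt[idx] <- rowsum(rep(1, length(ok)), cell[ok])[, 1L]
    wk_avg <- matrix(ifelse(obs_cnt > 0, obs_sum / pmax(obs_cnt, 1), NA),
                     n, tw, byrow = TRUE)
    prev_obs <- cbind(base, wk_avg[, -tw, drop = FALSE])
    for (t in seq_len(tw)[-1L]) {
      nas <- is.na(prev_obs[, t])
      prev_obs[nas, t] <- prev_obs[nas, t - 1L]
    }

    mk_X <- function(prev_vec, rows) {
      armd <- outer(arm[rows], ACTIVE_ARMS, "==") * 1
      # arm x previous-average interactions keep the imputation model
      # congenial with the moderation analysis
      cbind(1, prev_vec, week[rows] / tw,
            outer(dow[rows], 2:7, "==") * 1,
            armd, armd * prev_vec)
    }
    rows_obs <- which(!miss)
    Xo <- mk_X(prev_obs[cbind(pid[rows_obs], week[rows_obs])], rows_obs)
    yo <- av[rows_obs]
    qr_o <- qr(Xo)
    keep_cols <- qr_o$pivot[seq_len(qr_o$rank)]
    Xo <- Xo[, keep_cols, drop = FALSE]
    fit <- stats::lm.fit(Xo, yo)
    df_res <- length(yo) - ncol(Xo)
    rss <- sum(fit$residuals^2)
    xtx_inv <- chol2inv(chol(crossprod(Xo)))

    prep[[m]] <- list(none_missing = FALSE, sqrt_scale = sqrt_scale,
                      col = col, av = av, miss = miss, base = base,
                      betahat = fit$coefficients, xtx_inv = xtx_inv,
                      rss = rss, df_res = df_res, keep_cols = keep_cols,
                      mk_X = mk_X, prev_obs = prev_obs,
                      clip = switch(m, mood = c(1, 10),
                                    steps = c(0, sqrt(50000)),
                                    sleep = c(0, sqrt(1440))),
                      integer_valued = (m == "mood"))
  }

  completed <- vector("list", M)
  withr_seed(seed, "impute", {
    for (im in seq_len(M)) {
      comp <- daily
      for (m in measures) {
        pp <- prep[[m]]
        if (isTRUE(pp$none_missing)) next
        # posterior draws of (sigma^2, beta)
        sigma2 <- pp$rss / stats::rchisq(1, pp$df_res)
        cov_half <- chol(pp$xtx_inv * sigma2)
        beta <- pp$betahat + drop(crossprod(cov_half, stats::rnorm(length(pp$betahat))))
        av_new <- pp$av
        prev <- pp$base
        for (t in seq_len(tw)) {
          rows_t <- which(week == t)
          miss_t <- rows_t[pp$miss[rows_t]]
          if (length(miss_t)) {
            Xm <- pp$mk_X(prev[pid[miss_t]], miss_t)[, pp$keep_cols,
                                                     drop = FALSE]
            draw <- drop(Xm %*% beta) +
              stats::rnorm(length(miss_t), 0, sqrt(sigma2))
            if (pp$integer_valued) draw <- round(draw)
            draw <- pmin(pmax(draw, pp$clip[1L]), pp$clip[2L])
            av_new[miss_t] <- draw
          }
          wk <- rowsum(av_new[rows_t], pid[rows_t])
          prev[as.integer(rownames(wk))] <- wk[, 1L] / 7
        }
        comp[[pp$col]] <- if (pp$sqrt_scale) av_new^2 else av_new
      }
      completed[[im]] <- comp
    }
  })
  completed
}

#' Combine estimates across imputations with Rubin's rules
#'
#' Pooled estimate \eqn{\bar Q}, within-imputation variance \eqn{\bar U},
#' between-imputation variance \eqn{B} (denominator M-1), total variance
#' \eqn{T = \bar U + (1 + 1/M) B}, and degrees of freedom
#' \eqn{\nu = (M-1)(1 + \bar U / ((1+1/M)B))^2}. The p-value and 95% CI use
#' the t reference with \eqn{\nu} degrees of freedom (normal when B = 0).
#'
#' @param estimates Per-imputation point estimates.
#' @param variances Per-imputation squared standard errors.
#' @param dfcom Optional complete-data degrees of freedom; when supplied,
#'   the Barnard-Rubin small-sample adjustment
#'   \eqn{\nu_{adj} = (1/\nu + 1/\nu_{obs})^{-1}} with
#'   \eqn{\nu_{obs} = \frac{d+1}{d+3} d (1 - \gamma)},
#'   \eqn{\gamma = (1+1/M)B/T}, replaces the classic \eqn{\nu}.
#' @return Object of class `combined_estimate` with fields `m`, `qbar`,
#'   `ubar`, `b`, `t_var`, `df`, `se`, `statistic`, `p_value`, `ci`.
#' @export
rubin_combine <- function(estimates, variances, dfcom = NULL) {
  if (length(estimates) != length(variances)) {
    stop("`estimates` and `variances` must have the same length",
         call. = FALSE)
  }
  M <- length(estimates)
  if (M < 2L) stop("pooling needs at least 2 imputations", call. = FALSE)
  if (any(variances < 0)) stop("variances must be >= 0", call. = FALSE)
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- stats::var(estimates)
  t_var <- ubar + (1 + 1 / M) * b
  df <- if (b > 0) (M - 1) * (1 + ubar / ((1 + 1 / M) * b))^2 else Inf
  if (!is.null(dfcom) && is.finite(df)) {
    gamma <- (1 + 1 / M) * b / t_var
    df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - gamma)
    df <- 1 / (1 / df + 1 / df_obs)
  }
  se <- sqrt(t_var)
  stat <- if (se > 0) qbar / se else 0
  p <- if (is.finite(df)) 2 * stats::pt(-abs(stat), df) else
    2 * stats::pnorm(-abs(stat))
  crit <- if (is.finite(df)) stats::qt(0.975, df) else 1.96
  structure(
    list(m = M, qbar = qbar, ubar = ubar, b = b, t_var = t_var, df = df,
         se = se, statistic = stat, p_value = p,
         ci = c(lower = qbar - crit * se, upper = qbar + crit * se)),
    class = "combined_estimate")
}

#' @export
print.combined_estimate <- function(x, ...) {
  cat(sprintf(
    "Pooled over %d imputations: %.4f (SE %.4f; 95%% CI %.4f to %.4f; df %.1f; P=%.3g)\n",
    x$m, x$qbar, x$se, x$ci[["lower"]], x$ci[["upper"]], x$df, x$p_value))
  invisible(x)
}

#' Pool WCLS fits across imputed datasets
#'
#' Applies [rubin_combine()] coefficient-wise to a list of [fit_wcls()]
#' results from multiply imputed datasets.
#'
#' @param fits List of `wcls_fit` objects with identical coefficient sets.
#' @return Object of class `wcls_pooled`: pooled `coefficients`, diagonal
#'   total-variance `vcov`, per-coefficient Rubin `df`, and the list of
#'   per-coefficient `combined_estimate`s.
#' @export
pool_wcls <- function(fits) {
  nm <- names(fits[[1L]]$coefficients)
  est <- sapply(fits, function(f) f$coefficients[nm])
  vars <- sapply(fits, function(f) diag(f$vcov)[nm])
  combined <- lapply(seq_along(nm), function(j)
    rubin_combine(est[j, ], vars[j, ]))
  names(combined) <- nm
  coefs <- vapply(combined, `[[`, 0, "qbar")
  tvar <- vapply(combined, `[[`, 0, "t_var")
  vc <- diag(tvar, nrow = length(tvar), ncol = length(tvar))
  dimnames(vc) <- list(nm, nm)
  structure(
    list(coefficients = coefs, vcov = vc,
         rubin_df = vapply(combined, `[[`, 0, "df"),
         combined = combined, m = length(fits),
         n_clusters = fits[[1L]]$n_clusters, n_obs = fits[[1L]]$n_obs,
         mode = fits[[1L]]$mode, measure = fits[[1L]]$measure,
         transform = fits[[1L]]$transform),
    class = c("wcls_pooled", "wcls_fit"))
}
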