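#' Fit the weighted-and-centered least-squares moderation model
#'
#' Solves the weighted least-squares normal equations for the centered
#' design and computes the participant-clustered sandwich covariance
#' \deqn{B^{-1} M B^{-1}, \quad B = \sum_i X_i^\top W_i X_i, \quad
#'   M = \sum_i X_i^\top W_i r_i r_i^\top W_i X_i,}
#' summing over participant clusters \eqn{i} with residual vectors
#' \eqn{r_i}. Centering the treatment indicators at the known randomization
#' probabilities makes the moderation coefficients unbiased even when the
#' nuisance (control and moderator main-effect) terms are misspecified; the
#' sandwich accounts for within-participant correlation over weeks without
#' modelling it.
#'
#' @param design A [build_design_matrix()] object.
#' @return Object of class `wcls_fit`: `coefficients`, `vcov` (cluster
#'   sandwich), `n_clusters`, `n_obs`, `residuals`, plus design metadata.
#' @export
fit_wcls <- function(design) {
  stopifnot(inherits(design, "wcls_design"))
  X <- design$X
  y <- design$y
  w <- design$weights
  cl <- design$cluster
  n_clusters <- length(unique(cl))
  if (n_clusters < 2L) {
    stop("cluster-robust inference needs at least 2 participants",
         call. = FALSE)
  }
  sw <- sqrt(w)
  qr_x <- qr(X * sw)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_x, y * sw)
  r <- y - drop(X %*% beta)

  bread <- crossprod(X * sw)                    # sum_i X_i' W_i X_i
  score <- X * (w * r)                          # rows x_t' w_t r_t
  cl_score <- rowsum(score, cl)                 # per-cluster score sums
  meat <- crossprod(cl_score)
  binv <- solve(bread)
  vc <- binv %*% meat %*% binv
  vc <- (vc + t(vc)) / 2
  dimnames(vc) <- list(colnames(X), colnames(X))

  structure(
    list(coefficients = stats::setNames(beta, colnames(X)), vcov = vc,
         residuals = r, n_clusters = n_clusters, n_obs = nrow(X),
         arm_probs = design$arm_probs, mode = design$mode,
         treat_cols = design$treat_cols, inter_cols = design$inter_cols,
         controls = design$controls, measure = design$measure,
         transform = design$transform, n_dropped = design$n_dropped),
    class = "wcls_fit")
}

#' @export
coef.wcls_fit <- function(object, ...) object$coefficients

#' @export
vcov.wcls_fit <- function(object, ...) object$vcov

#' @export
print.wcls_fit <- function(x, ...) {
  cat("WCLS moderation fit (", x$mode, " treatment coding)\n", sep = "")
  cat("  ", x$n_obs, "participant-weeks in", x$n_clusters, "clusters\n")
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(estimate = x$coefficients, se = se,
                    z = x$coefficients / se)
  print(round(tab, 4))
  invisible(x)
}

#' Test a single WCLS coefficient against zero
#'
#' @param fit A [fit_wcls()] result, or any object with `coefficients` and
#'   `vcov` in the same shape (e.g. a pooled multiple-imputation fit uses
#'   its own method).
#' @param which Coefficient name, e.g. `"trt_activity:moderator"`.
#' @param reference `"normal"` (default; z statistic, CI = estimate
#'   +/- 1.96 SE) or `"t"` with clusters - parameters degrees of freedom.
#' @return Object of class `coef_test`: estimate, SE, statistic, p-value,
#'   95% CI.
#' @export
test_coefficient <- function(fit, which, reference = c("normal", "t")) {
  reference <- match.arg(reference)
  if (!which %in% names(fit$coefficients)) {
    stop("no coefficient named '", which, "'; available: ",
         paste(names(fit$coefficients), collapse = ", "), call. = FALSE)
  }
  if (inherits(fit, "wcls_pooled")) {
    ce <- fit$combined[[which]]
    return(structure(
      list(coefficient = which, estimate = ce$qbar, se = ce$se,
           statistic = ce$statistic, p_value = ce$p_value, ci = ce$ci,
           reference = sprintf("t (Rubin df %.1f)", ce$df)),
      class = "coef_test"))
  }
  est <- fit$coefficients[[which]]
  se <- sqrt(fit$vcov[which, which])
  stat <- if (se > 0) est / se else 0
  if (reference == "normal") {
    p <- 2 * stats::pnorm(-abs(stat))
    crit <- 1.96
  } else {
    df <- fit$n_clusters - length(fit$coefficients)
    p <- 2 * stats::pt(-abs(stat), df)
    crit <- stats::qt(0.975, df)
  }
  structure(
    list(coefficient = which, estimate = est, se = se, statistic = stat,
         p_value = min(max(p, 0), 1),
         ci = c(lower = est - crit * se, upper = est + crit * se),
         reference = reference),
    class = "coef_test")
}

#' @export
print.coef_test <- function(x, ...) {
  cat(sprintf("%s: %.4f (SE %.4f; 95%% CI %.4f to %.4f; P=%.3g)\n",
              x$coefficient, x$estimate, x$se, x$ci[["lower"]],
              x$ci[["upper"]], x$p_value))
  invisible(x)
}

#' Extract a category's moderated-effect coefficients
#'
#' Returns the treatment intercept \eqn{b_{0k}}, moderation slope
#' \eqn{b_{1k}} and their joint covariance for one notification category
#' (or for the pooled binary indicator).
#'
#' @param fit A [fit_wcls()] result.
#' @param category `"activity"`, `"sleep"`, `"mood"`, or `"binary"` for the
#'   pooled indicator of a binary-mode fit.
#' @return List `b0`, `b1`, `vcov` (2x2).
#' @export
moderation_coef <- function(fit, category) {
  if (identical(category, "binary") || fit$mode == "binary") {
    nm <- c("trt", "trt:moderator")
  } else {
    nm <- c(paste0("trt_", category), paste0("trt_", category, ":moderator"))
  }
  if (!all(nm %in% names(fit$coefficients))) {
    stop("fit has no coefficients for category '", category, "'",
         call. = FALSE)
  }
  list(b0 = fit$coefficients[[nm[1L]]], b1 = fit$coefficients[[nm[2L]]],
       vcov = fit$vcov[nm, nm])
}

#' Serialize a fit summary to JSON
#'
#' @param fit A [fit_wcls()] or [rubin_combine()]-pooled result.
#' @param path Output path.
#' @param seed Optional seed to record for provenance.
#' @export
write_fit_json <- function(fit, path, seed = NULL) {
  se <- sqrt(diag(fit$vcov))
  tests <- lapply(names(fit$coefficients), function(nm)
    unclass(test_coefficient(fit, nm))[c("estimate", "se", "statistic",
                                         "p_value", "ci")])
  names(tests) <- names(fit$coefficients)
  out <- list(coefficients = as.list(fit$coefficients),
              se = as.list(stats::setNames(se, names(fit$coefficients))),
              tests = tests, n_clusters = fit$n_clusters,
              n_obs = fit$n_obs, mode = fit$mode,
              measure = fit$measure, transform = fit$transform)
  if (!is.null(seed)) out$seed <- seed
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
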