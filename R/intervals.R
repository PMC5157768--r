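new_interval <- function(lower, upper, level, method, kind) {
  structure(
    list(lower = lower, upper = upper, level = level,
         method = method, kind = kind),
    class = "meta_interval"
  )
}

#' @export
print.meta_interval <- function(x, digits = 4, ...) {
  cat(sprintf("%s %.0f%% %s interval: [%s; %s]\n", x$method, 100 * x$level,
              x$kind, signif(x$lower, digits), signif(x$upper, digits)))
  invisible(x)
}

#' Confidence interval for the mean effect
#'
#' \eqn{\hat\theta \pm t_{df;\alpha/2}\sqrt{V}} where V and df come from
#' the supplied method-specific variance estimate; `df = Inf` yields the
#' conventional standard-normal quantile.
#'
#' @param fit A [fit_reml()] result.
#' @param ve A `"variance_estimate"` (from [meta_variance()] or one of the
#'   `variance_*()` / [kr_adjust()] constructors).
#' @param level Coverage level in (0, 1); default 0.95.
#' @return A `"meta_interval"` with `kind = "confidence"`.
#' @examples
#' fit <- fit_reml(dbp_meta("post"))
#' confidence_interval(fit, variance_hk(fit$studies, fit))
#' @export
confidence_interval <- function(fit, ve, level = 0.95) {
  stopifnot(inherits(fit, "reml_fit"), inherits(ve, "variance_estimate"))
  if (!is.finite(level) || level <= 0 || level >= 1) {
    stop("'level' must be in (0, 1)", call. = FALSE)
  }
  crit <- stats::qt(1 - (1 - level) / 2, df = ve$df)
  half <- crit * sqrt(ve$value)
  new_interval(fit$theta - half, fit$theta + half, level, ve$method,
               "confidence")
}

#' Prediction interval for the effect in a new study
#'
#' The Higgins-type construction
#' \eqn{\hat\theta \pm t_{df';\alpha/2}\sqrt{\hat\tau^2 + V}}, combining the
#' between-study variance with the method's variance V of the pooled mean.
#' The reference degrees of freedom are `k - 2` for the N, HK, HK2, SJ and
#' SJ2 methods (so `k >= 3` is required) and `df_KR - 1` for the
#' Kenward-Roger method (requiring `df_KR > 1`).
#'
#' @inheritParams confidence_interval
#' @return A `"meta_interval"` with `kind = "prediction"`.
#' @export
prediction_interval <- function(fit, ve, level = 0.95) {
  stopifnot(inherits(fit, "reml_fit"), inherits(ve, "variance_estimate"))
  if (!is.finite(level) || level <= 0 || level >= 1) {
    stop("'level' must be in (0, 1)", call. = FALSE)
  }
  k <- fit$studies$k
  df_pi <- if (inherits(ve, "kr_adjustment")) ve$df - 1 else k - 2
  if (df_pi <= 0) {
    stop("prediction interval undefined for method ", ve$method, ": ",
         if (inherits(ve, "kr_adjustment")) {
           paste0("Kenward-Roger df - 1 = ", signif(df_pi, 4), " <= 0")
         } else {
           paste0("needs k - 2 > 0, but k = ", k)
         }, call. = FALSE)
  }
  crit <- stats::qt(1 - (1 - level) / 2, df = df_pi)
  half <- crit * sqrt(fit$tau2 + ve$value)
  new_interval(fit$theta - half, fit$theta + half, level, ve$method,
               "prediction")
}

#' Summary of all interval methods for one meta-analysis
#'
#' Fits the random-effects model by REML once and tabulates, per method,
#' the pooled estimate, confidence interval, prediction interval and the
#' degrees of freedom used for each, alongside the heterogeneity summaries.
#' Prediction intervals that a method refuses (fewer than 3 studies for the
#' k-2 rule, or a Kenward-Roger df not exceeding 1) are reported as `NA`.
#'
#' @param studies A [study_set()].
#' @param level Coverage level in (0, 1); default 0.95.
#' @param methods Subset of [meta_methods()] to report (default all six).
#' @param tol,max_iter Passed to [fit_reml()].
#'
#' @return A data frame with one row per method and columns `method`,
#'   `estimate`, `ci_low`, `ci_high`, `pi_low`, `pi_high`, `tau2`, `i2`,
#'   `df_ci`, `df_pi`. The REML fit is attached as attribute `"fit"`.
#' @examples
#' meta_intervals(dbp_meta("post"))
#' @export
meta_intervals <- function(studies, level = 0.95, methods = meta_methods(),
                           tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(studies, "study_set"))
  for (m in methods) check_method(m)
  fit <- fit_reml(studies, tol = tol, max_iter = max_iter)
  i2 <- i_squared(studies)
  rows <- lapply(methods, function(m) {
    ve <- meta_variance(m, studies, fit)
    ci <- confidence_interval(fit, ve, level)
    pi <- tryCatch(prediction_interval(fit, ve, level),
                   error = function(e) NULL)
    data.frame(method = m,
               estimate = fit$theta,
               ci_low = ci$lower, ci_high = ci$upper,
               pi_low = if (is.null(pi)) NA_real_ else pi$lower,
               pi_high = if (is.null(pi)) NA_real_ else pi$upper,
               tau2 = fit$tau2, i2 = i2,
               df_ci = ve$df,
               df_pi = if (is.null(pi)) NA_real_ else {
                 if (inherits(ve, "kr_adjustment")) ve$df - 1 else studies$k - 2
               })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}
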