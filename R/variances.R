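#' Interval-method identifiers
#'
#' The closed set of method tags used throughout the package:
#' `"N"` (conventional normal-quantile interval), `"HK"` (Hartung-Knapp),
#' `"HK2"` (modified Hartung-Knapp, never narrower than conventional),
#' `"SJ"` (Sidik-Jonkman robust variance), `"SJ2"` (bias-corrected
#' Sidik-Jonkman) and `"KR"` (Kenward-Roger).
#'
#' @return Character vector of the six method ids, in reporting order.
#' @export
meta_methods <- function() c("N", "HK", "HK2", "SJ", "SJ2", "KR")

check_method <- function(method) {
  if (length(method) != 1L || !method %in% meta_methods()) {
    stop("unknown method '", paste(method, collapse = ","),
         "'; must be one of ", paste(meta_methods(), collapse = ", "),
         call. = FALSE)
  }
  method
}

new_variance_estimate <- function(method, value, df, q_factor = NULL) {
  structure(
    list(method = method, value = value, df = df, q_factor = q_factor),
    class = "variance_estimate"
  )
}

#' @export
print.variance_estimate <- function(x, ...) {
  cat(sprintf("%s variance of the pooled effect: %.6g (df = %s)\n",
              x$method, x$value,
              if (is.infinite(x$df)) "Inf" else format(x$df)))
  invisible(x)
}

#' Conventional variance of the pooled effect
#'
#' The model-based value \eqn{\hat\sigma_\theta^2 = 1/\sum w_i} at the
#' REML estimate of tau-squared, paired with a standard-normal reference
#' (`df = Inf`).
#'
#' @param fit A [fit_reml()] result.
#' @return A `"variance_estimate"` with `method = "N"`.
#' @export
variance_n <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  new_variance_estimate("N", fit$var_theta, Inf)
}

hk_q <- function(studies, fit) {
  sum(fit$weights * (studies$effects - fit$theta)^2) / (studies$k - 1)
}

#' Hartung-Knapp variance
#'
#' Rescales the conventional variance by the weighted residual mean square
#' \eqn{q = \sum_i w_i(\hat\theta_i - \hat\theta)^2/(k-1)} and uses a
#' t reference with k-1 degrees of freedom:
#' \eqn{\mathrm{Var}_{HK} = q\,\hat\sigma_\theta^2}.
#'
#' @param studies A [study_set()] (the data `fit` was fitted to).
#' @param fit A [fit_reml()] result.
#' @return A `"variance_estimate"` with `method = "HK"`; `q_factor` holds q.
#' @export
variance_hk <- function(studies, fit) {
  stopifnot(inherits(studies, "study_set"), inherits(fit, "reml_fit"))
  q <- hk_q(studies, fit)
  new_variance_estimate("HK", q * fit$var_theta, studies$k - 1, q_factor = q)
}

#' Modified Hartung-Knapp variance
#'
#' Truncates the Hartung-Knapp factor at one, \eqn{q^* = \max\{1, q\}},
#' so that the resulting interval is never shorter than the conventional
#' one: \eqn{\mathrm{Var}_{HK}^* = q^*\hat\sigma_\theta^2}.
#'
#' @inheritParams variance_hk
#' @return A `"variance_estimate"` with `method = "HK2"`; `q_factor` holds
#'   the truncated factor.
#' @export
variance_hk2 <- function(studies, fit) {
  stopifnot(inherits(studies, "study_set"), inherits(fit, "reml_fit"))
  qstar <- max(1, hk_q(studies, fit))
  new_variance_estimate("HK2", qstar * fit$var_theta, studies$k - 1,
                        q_factor = qstar)
}

#' Sidik-Jonkman robust (sandwich) variance
#'
#' \eqn{\mathrm{Var}_{SJ} = \sum_i w_i^2(\hat\theta_i-\hat\theta)^2 /
#' (\sum_i w_i)^2}, a sandwich-type estimator robust to misspecification of
#' the weights, with a t reference on k-1 degrees of freedom.
#'
#' @inheritParams variance_hk
#' @return A `"variance_estimate"` with `method = "SJ"`.
#' @export
variance_sj <- function(studies, fit) {
  stopifnot(inherits(studies, "study_set"), inherits(fit, "reml_fit"))
  w <- fit$weights
  r <- studies$effects - fit$theta
  new_variance_estimate("SJ", sum(w^2 * r^2) / sum(w)^2, studies$k - 1)
}

#' Bias-corrected Sidik-Jonkman variance
#'
#' Inflates each squared residual of the robust estimator by
#' \eqn{(1-h_i)^{-1}}, where \eqn{h_i = w_i/\sum_j w_j} is the leverage
#' (hat value) of study i in the weighted-least-squares fit of the common
#' mean:
#' \eqn{\mathrm{Var}_{SJ}^* = \sum_i w_i^2(1-h_i)^{-1}
#' (\hat\theta_i-\hat\theta)^2/(\sum_i w_i)^2}. This correction removes the
#' downward small-k bias of the uncorrected sandwich and always yields
#' \eqn{\mathrm{Var}_{SJ}^* \ge \mathrm{Var}_{SJ}}.
#'
#' @inheritParams variance_hk
#' @return A `"variance_estimate"` with `method = "SJ2"`.
#' @export
variance_sj2 <- function(studies, fit) {
  stopifnot(inherits(studies, "study_set"), inherits(fit, "reml_fit"))
  w <- fit$weights
  h <- w / sum(w)
  if (any(h >= 1)) {
    stop("leverage h_i >= 1 for study '",
         studies$labels[which(h >= 1)[1L]],
         "': bias-corrected Sidik-Jonkman variance undefined", call. = FALSE)
  }
  r <- studies$effects - fit$theta
  new_variance_estimate("SJ2", sum(w^2 * r^2 / (1 - h)) / sum(w)^2,
                        studies$k - 1)
}

#' Kenward-Roger adjustment
#'
#' Adjusts the variance of the pooled effect for the uncertainty in the
#' REML estimate of tau-squared using the expected information, and sets a
#' matching (typically fractional) degrees of freedom. With weight moments
#' \eqn{w_{j\bullet} = \sum_i w_i^j}:
#' \deqn{I_E = \tfrac{w_{2\bullet}}{2} - \tfrac{w_{3\bullet}}{w_{1\bullet}}
#'   + \tfrac12\Big(\tfrac{w_{2\bullet}}{w_{1\bullet}}\Big)^2,\quad
#'   \mathrm{Var}_{KR} = \frac{1}{w_{1\bullet}} +
#'   \frac{2\,(w_{3\bullet} - w_{2\bullet}^2/w_{1\bullet})}
#'        {w_{1\bullet}^2 I_E},\quad
#'   \nu = \frac{2 I_E}{\mathrm{Var}_{KR}^2\, w_{2\bullet}^2}.}
#'
#' @inheritParams variance_hk
#' @return An object of classes `"kr_adjustment"` and `"variance_estimate"`
#'   with `value` (\eqn{\mathrm{Var}_{KR}}), `df` (\eqn{\nu}),
#'   `expected_info` and `w_moments` (\eqn{w_{1\bullet}, w_{2\bullet},
#'   w_{3\bullet}}).
#' @examples
#' kr_adjust(dbp_meta("pre"), fit_reml(dbp_meta("pre")))$df
#' @export
kr_adjust <- function(studies, fit) {
  stopifnot(inherits(studies, "study_set"), inherits(fit, "reml_fit"))
  w <- fit$weights
  w1 <- sum(w); w2 <- sum(w^2); w3 <- sum(w^3)
  ie <- w2 / 2 - w3 / w1 + 0.5 * (w2 / w1)^2
  if (!is.finite(ie) || ie <= 0) {
    stop("Kenward-Roger expected information non-positive (I_E = ", ie,
         "; w moments ", paste(signif(c(w1, w2, w3), 6), collapse = ", "),
         ")", call. = FALSE)
  }
  var_kr <- 1 / w1 + 2 * (w3 - w2^2 / w1) / (w1^2 * ie)
  if (!is.finite(var_kr) || var_kr <= 0) {
    stop("Kenward-Roger adjusted variance non-positive (Var_KR = ", var_kr,
         ")", call. = FALSE)
  }
  df_kr <- 2 * ie / (var_kr^2 * w2^2)
  structure(
    list(method = "KR", value = var_kr, df = df_kr, q_factor = NULL,
         expected_info = ie, w_moments = c(w1 = w1, w2 = w2, w3 = w3)),
    class = c("kr_adjustment", "variance_estimate")
  )
}

#' Variance estimate for a named method
#'
#' Dispatches to [variance_n()], [variance_hk()], [variance_hk2()],
#' [variance_sj()], [variance_sj2()] or [kr_adjust()].
#'
#' @param method One of [meta_methods()].
#' @inheritParams variance_hk
#' @return A `"variance_estimate"`.
#' @export
meta_variance <- function(method, studies, fit) {
  switch(check_method(method),
         N = variance_n(fit),
         HK = variance_hk(studies, fit),
         HK2 = variance_hk2(studies, fit),
         SJ = variance_sj(studies, fit),
         SJ2 = variance_sj2(studies, fit),
         KR = kr_adjust(studies, fit))
}
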