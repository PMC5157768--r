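#' Restricted log-likelihood of the between-study variance
#'
#' Profile restricted log-likelihood of the two-level normal model at a
#' given between-study variance `tau2`, up to an additive constant:
#' \deqn{\ell_R(\tau^2) = -\tfrac12\Big[\sum_i \log(\hat\sigma_i^2+\tau^2)
#'   + \log \sum_i w_i + \sum_i w_i(\hat\theta_i - \hat\theta(\tau^2))^2\Big]}
#' with \eqn{w_i = 1/(\hat\sigma_i^2+\tau^2)} and \eqn{\hat\theta(\tau^2)}
#' the generalised-least-squares mean at that `tau2`. Used as the
#' optimisation oracle for [fit_reml()].
#'
#' @param studies A [study_set()].
#' @param tau2 Non-negative between-study variance at which to evaluate.
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_log_likelihood <- function(studies, tau2) {
  stopifnot(inherits(studies, "study_set"))
  if (!is.finite(tau2) || tau2 < 0) {
    stop("'tau2' must be a finite non-negative number", call. = FALSE)
  }
  w <- 1 / (studies$variances + tau2)
  theta <- sum(w * studies$effects) / sum(w)
  -0.5 * (sum(log(studies$variances + tau2)) + log(sum(w)) +
            sum(w * (studies$effects - theta)^2))
}

#' Pooled effect and its conventional variance at a given tau2
#'
#' Inverse-variance (generalised least squares) pooling with weights
#' \eqn{w_i = 1/(\hat\sigma_i^2+\tau^2)}:
#' \eqn{\hat\theta = \sum w_i\hat\theta_i / \sum w_i} and
#' \eqn{\hat\sigma_\theta^2 = 1/\sum w_i}.
#'
#' @inheritParams restricted_log_likelihood
#' @return A list with `theta` and `var_theta`.
#' @export
pooled_estimate <- function(studies, tau2) {
  stopifnot(inherits(studies, "study_set"))
  if (!is.finite(tau2) || tau2 < 0) {
    stop("'tau2' must be a finite non-negative number", call. = FALSE)
  }
  w <- 1 / (studies$variances + tau2)
  list(theta = sum(w * studies$effects) / sum(w), var_theta = 1 / sum(w))
}

#' Cochran's Q statistic
#'
#' Weighted residual sum of squares about the fixed-effect (`tau2 = 0`)
#' pooled mean, with fixed-effect weights \eqn{1/\hat\sigma_i^2}.
#'
#' @param studies A [study_set()].
#' @return Q (non-negative scalar).
#' @export
q_statistic <- function(studies) {
  stopifnot(inherits(studies, "study_set"))
  w <- 1 / studies$variances
  theta_fe <- sum(w * studies$effects) / sum(w)
  sum(w * (studies$effects - theta_fe)^2)
}

#' I-squared heterogeneity percentage
#'
#' Q-based definition: \eqn{I^2 = 100\,\max(0, (Q - (k-1))/Q)}, the
#' percentage of total variation in the effect estimates attributable to
#' between-study heterogeneity rather than sampling error; 0 when Q = 0.
#'
#' @param studies A [study_set()].
#' @return I-squared in percent, in \[0, 100\].
#' @export
i_squared <- function(studies) {
  q <- q_statistic(studies)
  if (q <= 0) return(0)
  100 * max(0, (q - (studies$k - 1)) / q)
}

#' DerSimonian-Laird moment estimate of the between-study variance
#'
#' \eqn{\hat\tau^2_{DL} = \max\{0, (Q-(k-1))/(S_1 - S_2/S_1)\}} with
#' \eqn{S_j = \sum_i \hat\sigma_i^{-2j}}. Used here only as the starting
#' value for the REML iteration.
#'
#' @param studies A [study_set()].
#' @return Non-negative moment estimate of tau-squared.
#' @export
dl_tau2 <- function(studies) {
  stopifnot(inherits(studies, "study_set"))
  w <- 1 / studies$variances
  denom <- sum(w) - sum(w^2) / sum(w)
  if (denom <= 0) return(0)
  max(0, (q_statistic(studies) - (studies$k - 1)) / denom)
}

#' Fit the random-effects model by restricted maximum likelihood
#'
#' Estimates the between-study variance of the two-level normal model
#' \deqn{\hat\theta_i \sim N(\theta_i, \hat\sigma_i^2), \qquad
#'       \theta_i \sim N(\theta, \tau^2)}
#' by REML, using the standard fixed-point iteration
#' \deqn{\tau^2 \leftarrow \max\Big\{0,\;
#'   \frac{\sum_i w_i^2[(\hat\theta_i-\hat\theta)^2 - \hat\sigma_i^2]}
#'        {\sum_i w_i^2} + \frac{1}{\sum_i w_i}\Big\}}
#' started from the DerSimonian-Laird moment estimate and truncated at
#' zero. The pooled mean and its conventional variance are the GLS values
#' at the converged `tau2`.
#'
#' @param studies A [study_set()].
#' @param tol Convergence tolerance on the change in `tau2` between
#'   successive iterates (default `1e-10`).
#' @param max_iter Maximum number of iterations (default 200). If reached,
#'   the last iterate is returned with `converged = FALSE`.
#'
#' @return An object of class `"reml_fit"`: a list with `tau2`, `theta`,
#'   `var_theta`, `weights` (the \eqn{w_i = 1/(\hat\sigma_i^2+\hat\tau^2)}),
#'   `converged`, `n_iter`, and the input `studies`.
#' @examples
#' fit <- fit_reml(dbp_meta("post"))
#' c(theta = fit$theta, tau2 = fit$tau2)
#' @export
fit_reml <- function(studies, tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(studies, "study_set"))
  if (!is.finite(tol) || tol <= 0) stop("'tol' must be > 0", call. = FALSE)
  y <- studies$effects
  v <- studies$variances
  tau2 <- dl_tau2(studies)
  converged <- FALSE
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    w <- 1 / (v + tau2)
    theta <- sum(w * y) / sum(w)
    tau2_new <- max(0, sum(w^2 * ((y - theta)^2 - v)) / sum(w^2) + 1 / sum(w))
    if (!is.finite(tau2_new)) {
      contrib <- w^2 * ((y - theta)^2 - v)
      bad <- which(!is.finite(contrib))[1L]
      stop("non-finite restricted likelihood contribution from study '",
           studies$labels[if (is.na(bad)) 1L else bad], "'", call. = FALSE)
    }
    if (abs(tau2_new - tau2) < tol) {
      tau2 <- tau2_new
      converged <- TRUE
      break
    }
    tau2 <- tau2_new
    if (n_iter >= max_iter) break
  }
  w <- 1 / (v + tau2)
  structure(
    list(tau2 = tau2,
         theta = sum(w * y) / sum(w),
         var_theta = 1 / sum(w),
         weights = w,
         converged = converged,
         n_iter = n_iter,
         studies = studies),
    class = "reml_fit"
  )
}

#' @export
print.reml_fit <- function(x, digits = 4, ...) {
  cat("Random-effects meta-analysis (REML), k =", x$studies$k, "studies\n")
  cat("  pooled effect theta  =", signif(x$theta, digits),
      " (se", signif(sqrt(x$var_theta), digits), ")\n")
  cat("  between-study tau^2  =", signif(x$tau2, digits), "\n")
  cat("  I^2                  =",
      sprintf("%.1f%%", i_squared(x$studies)), "\n")
  if (!x$converged) {
    cat("  WARNING: REML iteration did not converge in", x$n_iter,
        "iterations\n")
  }
  invisible(x)
}
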