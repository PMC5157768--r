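#' Define a simulation scenario
#'
#' A scenario fixes the data-generating process for synthetic
#' meta-analyses: `k` studies whose true effects are drawn from
#' \eqn{N(\theta, \tau^2)} with \eqn{\tau^2 = \nu\,\sigma^2}; within-study
#' variance estimates drawn from a scaled chi-square,
#' \eqn{\hat\sigma_i^2 \sim \sigma_i^2\,\chi^2_{n-1}/(n-1)}, centred on the
#' study's true variance \eqn{\sigma_i^2}; and effect estimates
#' \eqn{\hat\theta_i \sim N(\theta_i, \sigma_i^2)} drawn with the *true*
#' variance. `n_within` plays the role of an average within-study sample
#' size and controls how variable the variance estimates are.
#'
#' The `pattern` sets study-size imbalance through the true variances:
#' `"balanced"` gives every study \eqn{\sigma^2}; `"one_large"` gives study
#' 1 a variance \eqn{\sigma^2/10} (a study 10 times larger); `"one_small"`
#' gives study 1 \eqn{10\sigma^2}; `"mixture"` alternates
#' \eqn{\sigma^2/10} and \eqn{10\sigma^2} across studies, starting large.
#' The imbalance is not compensated elsewhere, so unbalanced patterns
#' change the effective degree of heterogeneity.
#'
#' @param k Number of studies (>= 2).
#' @param nu_ratio Heterogeneity ratio \eqn{\nu = \tau^2/\sigma^2}.
#' @param theta True mean effect (default 1).
#' @param sigma2 Average within-study variance (default 0.1).
#' @param n_within Within-study sample size controlling the chi-square
#'   degrees of freedom `n_within - 1` (default 30).
#' @param pattern One of `"balanced"`, `"one_large"`, `"one_small"`,
#'   `"mixture"`.
#' @param seed Optional integer seed recorded with the scenario and used
#'   by [run_scenario()].
#' @return An object of class `"meta_scenario"`; `tau2` is derived as
#'   `nu_ratio * sigma2`.
#' @examples
#' meta_scenario(k = 5, nu_ratio = 10)
#' @export
meta_scenario <- function(k, nu_ratio, theta = 1, sigma2 = 0.1,
                          n_within = 30L,
                          pattern = c("balanced", "one_large", "one_small",
                                      "mixture"),
                          seed = NULL) {
  pattern <- match.arg(pattern)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("'k' must be an integer >= 2", call. = FALSE)
  if (!is.finite(sigma2) || sigma2 <= 0) {
    stop("'sigma2' must be > 0", call. = FALSE)
  }
  if (!is.finite(nu_ratio) || nu_ratio <= 0) {
    stop("'nu_ratio' must be > 0", call. = FALSE)
  }
  if (!is.finite(n_within) || n_within < 2) {
    stop("'n_within' must be >= 2", call. = FALSE)
  }
  structure(
    list(k = k, theta = theta, sigma2 = sigma2, nu_ratio = nu_ratio,
         tau2 = nu_ratio * sigma2, n_within = as.integer(n_within),
         pattern = pattern, seed = seed),
    class = "meta_scenario"
  )
}

#' @export
print.meta_scenario <- function(x, ...) {
  cat(sprintf(
    "Scenario: k = %d, theta = %g, sigma2 = %g, nu = %g (tau2 = %g), n = %d, %s\n",
    x$k, x$theta, x$sigma2, x$nu_ratio, x$tau2, x$n_within, x$pattern))
  invisible(x)
}

#' True within-study variances implied by a scenario's imbalance pattern
#'
#' @param scenario A [meta_scenario()].
#' @return Numeric vector of length `k` with each study's true variance
#'   \eqn{\sigma_i^2}.
#' @examples
#' study_variances(meta_scenario(k = 4, nu_ratio = 1, pattern = "one_small"))
#' @export
study_variances <- function(scenario) {
  stopifnot(inherits(scenario, "meta_scenario"))
  s2 <- scenario$sigma2
  k <- scenario$k
  switch(scenario$pattern,
         balanced = rep(s2, k),
         one_large = c(s2 / 10, rep(s2, k - 1L)),
         one_small = c(10 * s2, rep(s2, k - 1L)),
         mixture = rep(c(s2 / 10, 10 * s2), length.out = k),
         stop("unknown pattern '", scenario$pattern, "'", call. = FALSE))
}

#' Simulate one meta-analysis data set
#'
#' Draws, from the current RNG state and in this fixed order: the `k` true
#' study effects \eqn{\theta_i \sim N(\theta, \tau^2)}; the `k` estimated
#' within-study variances
#' \eqn{\hat\sigma_i^2 = \sigma_i^2 X_i/(n-1)}, \eqn{X_i \sim \chi^2_{n-1}};
#' the `k` effect estimates \eqn{\hat\theta_i \sim N(\theta_i, \sigma_i^2)}
#' (note: true variance, not the estimate); and finally one new-study
#' effect from \eqn{N(\theta, \tau^2)} for assessing predictive coverage.
#'
#' @param scenario A [meta_scenario()]. Seeding is the caller's
#'   responsibility (see [run_scenario()] for substream management);
#'   wrapping the call in `set.seed()` makes the draw reproducible.
#' @return An object of class `"simulated_meta"`: a list with `studies`
#'   (a [study_set()] holding the estimates the analyst would see),
#'   `true_effects`, `true_variances` and `new_effect`.
#' @examples
#' set.seed(1)
#' sim <- simulate_meta(meta_scenario(k = 5, nu_ratio = 10))
#' sim$studies
#' @export
simulate_meta <- function(scenario) {
  stopifnot(inherits(scenario, "meta_scenario"))
  k <- scenario$k
  sigma2_i <- study_variances(scenario)
  theta_i <- stats::rnorm(k, scenario$theta, sqrt(scenario$tau2))
  df <- scenario$n_within - 1L
  sigma2_hat <- sigma2_i * stats::rchisq(k, df = df) / df
  # chi-square draws are almost surely positive; guard against underflow
  stopifnot(all(sigma2_hat > 0))
  theta_hat <- stats::rnorm(k, theta_i, sqrt(sigma2_i))
  new_effect <- stats::rnorm(1L, scenario$theta, sqrt(scenario$tau2))
  structure(
    list(studies = study_set(theta_hat, var = sigma2_hat),
         true_effects = theta_i,
         true_variances = sigma2_i,
         new_effect = new_effect),
    class = "simulated_meta"
  )
}
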