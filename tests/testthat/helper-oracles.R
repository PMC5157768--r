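# shared fixtures and independent oracles

toy3 <- function() {
  study_set(c(0.5, -0.2, 0.3), se = c(0.2, 0.3, 0.25),
            labels = c("a", "b", "c"))
}

# random study set with heterogeneity, reproducible under the caller's seed
rand_studies <- function(k) {
  tau2 <- stats::runif(1, 0, 0.5)
  v <- stats::runif(k, 0.02, 0.5)
  y <- stats::rnorm(k, 0.3, sqrt(tau2)) + stats::rnorm(k, 0, sqrt(v))
  study_set(y, var = v)
}

# dense grid-search argmax of the restricted log-likelihood: the
# independent optimisation oracle for fit_reml
grid_tau2 <- function(studies, upper = NULL, n_grid = 4001L) {
  if (is.null(upper)) {
    upper <- max(1, 5 * stats::var(studies$effects))
  }
  grid <- seq(0, upper, length.out = n_grid)
  ll <- vapply(grid, function(t2) restricted_log_likelihood(studies, t2),
               numeric(1))
  list(tau2 = grid[which.max(ll)], step = grid[2L] - grid[1L])
}

interval_width <- function(int) int$upper - int$lower
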