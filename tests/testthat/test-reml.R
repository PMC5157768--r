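test_that("restricted log-likelihood behaves on degenerate and large inputs", {
  pair <- study_set(c(1, 1), se = c(0.2, 0.2))
  expect_gt(restricted_log_likelihood(pair, 0),
            restricted_log_likelihood(pair, 1))
  expect_error(restricted_log_likelihood(pair, -0.1), "non-negative")

  s <- toy3()
  lls <- vapply(c(0, 1e-3, 0.1, 1, 100, 1e6),
                function(t2) restricted_log_likelihood(s, t2), numeric(1))
  expect_true(all(is.finite(lls)))
})

test_that("REML tau2 matches the grid-search oracle on random study sets", {
  set.seed(401)
  for (k in c(2, 3, 5, 8, 10)) {
    for (rep in 1:4) {
      s <- rand_studies(k)
      fit <- fit_reml(s)
      expect_true(fit$converged)
      oracle <- grid_tau2(s)
      expect_lt(abs(fit$tau2 - oracle$tau2), oracle$step + 1e-6)
    }
  }
})

test_that("REML fit satisfies its self-consistency invariants", {
  set.seed(402)
  s <- rand_studies(6)
  fit <- fit_reml(s)
  expect_equal(fit$weights, 1 / (s$variances + fit$tau2))
  expect_equal(fit$var_theta, 1 / sum(fit$weights))
  expect_equal(fit$theta,
               sum(fit$weights * s$effects) / sum(fit$weights))
  expect_gte(fit$tau2, 0)
})

test_that("identical effects give tau2 = 0 and the common value", {
  s <- study_set(rep(2.5, 4), se = c(0.1, 0.3, 0.2, 0.5))
  fit <- fit_reml(s)
  expect_equal(fit$tau2, 0)
  expect_equal(fit$theta, 2.5)
  expect_equal(q_statistic(s), 0)
  expect_equal(i_squared(s), 0)
  expect_equal(dl_tau2(s), 0)
})

test_that("REML agrees with metafor on random data and the DBP fixtures", {
  skip_if_not_installed("metafor")
  check <- function(s) {
    fit <- fit_reml(s)
    m <- metafor::rma(s$effects, s$variances, method = "REML",
                      control = list(tol = 1e-10))
    # the two solvers use different convergence criteria; agreement to
    # 1e-4 relative is far below any reported precision
    expect_equal(fit$tau2, m$tau2, tolerance = 1e-4)
    expect_equal(fit$theta, as.numeric(m$b), tolerance = 1e-6)
    expect_equal(sqrt(fit$var_theta), as.numeric(m$se), tolerance = 1e-5)
  }
  set.seed(403)
  for (k in c(3, 7)) check(rand_studies(k))
  check(dbp_meta("pre"))
  check(dbp_meta("post"))
})

test_that("pooled_estimate is inverse-variance weighting", {
  # equal variances, tau2 = 0: arithmetic mean with variance v/k
  s <- study_set(c(1, 2, 6), var = c(0.5, 0.5, 0.5))
  pe <- pooled_estimate(s, 0)
  expect_equal(pe$theta, 3)
  expect_equal(pe$var_theta, 0.5 / 3)

  # explicit weighted-mean arithmetic at tau2 = 0.1
  s2 <- study_set(c(0.4, -0.1, 0.2), var = c(0.04, 0.09, 0.01))
  w <- c(1 / 0.14, 1 / 0.19, 1 / 0.11)
  pe2 <- pooled_estimate(s2, 0.1)
  expect_equal(pe2$theta, (0.4 * w[1] - 0.1 * w[2] + 0.2 * w[3]) / sum(w))
  expect_equal(pe2$var_theta, 1 / sum(w))

  # equal within-study variances: theta is the unweighted mean at any tau2
  s3 <- study_set(c(-1, 0.5, 2, 4), var = rep(0.3, 4))
  for (t2 in c(0, 0.2, 5)) {
    expect_equal(pooled_estimate(s3, t2)$theta, mean(s3$effects))
  }
})

test_that("conventional variance never increases when a study gains precision", {
  set.seed(404)
  s <- rand_studies(5)
  for (t2 in c(0, 0.3)) {
    base <- pooled_estimate(s, t2)$var_theta
    for (i in 1:5) {
      v2 <- s$variances
      v2[i] <- v2[i] / 2
      shrunk <- pooled_estimate(study_set(s$effects, var = v2), t2)$var_theta
      expect_lte(shrunk, base)
    }
  }
})

test_that("Q and the DL moment estimator match direct computation", {
  s <- toy3()
  w <- 1 / s$variances
  th <- sum(w * s$effects) / sum(w)
  expect_equal(q_statistic(s), sum(w * (s$effects - th)^2))

  s4 <- study_set(c(0.1, 0.9, -0.4, 0.6), var = c(0.05, 0.1, 0.2, 0.08))
  w4 <- 1 / s4$variances
  th4 <- sum(w4 * s4$effects) / sum(w4)
  q4 <- sum(w4 * (s4$effects - th4)^2)
  expect_equal(dl_tau2(s4),
               max(0, (q4 - 3) / (sum(w4) - sum(w4^2) / sum(w4))))

  # equal variances v: DL reduces to max(0, sample variance - v)
  se <- study_set(c(0.2, 1.4, -0.6, 0.8), var = rep(0.1, 4))
  expect_equal(dl_tau2(se), max(0, stats::var(se$effects) - 0.1))
})

test_that("I-squared is location and scale invariant and truncates at zero", {
  set.seed(405)
  s <- rand_studies(6)
  i2 <- i_squared(s)
  shifted <- study_set(s$effects + 3.7, var = s$variances)
  scaled <- study_set(2.5 * s$effects, var = 2.5^2 * s$variances)
  expect_equal(i_squared(shifted), i2)
  expect_equal(i_squared(scaled), i2)

  # near-homogeneous data with Q below k - 1 truncates to zero
  tight <- study_set(c(0.50, 0.501, 0.499), var = rep(0.2, 3))
  expect_lt(q_statistic(tight), 2)
  expect_equal(i_squared(tight), 0)
})

test_that("fit_reml reports non-convergence instead of failing", {
  set.seed(406)
  s <- rand_studies(5)
  fit <- fit_reml(s, max_iter = 1L)
  expect_false(fit$converged)
  expect_identical(fit$n_iter, 1L)
  expect_true(is.finite(fit$tau2))
})
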