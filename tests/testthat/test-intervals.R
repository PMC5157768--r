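test_that("confidence intervals use the method's quantile and variance", {
  s <- toy3()
  fit <- fit_reml(s)

  ci_n <- confidence_interval(fit, variance_n(fit))
  expect_equal(ci_n$lower,
               fit$theta - stats::qnorm(0.975) * sqrt(fit$var_theta))
  expect_equal(ci_n$upper,
               fit$theta + stats::qnorm(0.975) * sqrt(fit$var_theta))

  hk <- variance_hk(s, fit)
  ci_hk <- confidence_interval(fit, hk, level = 0.9)
  expect_equal(ci_hk$upper - ci_hk$lower,
               2 * stats::qt(0.95, 2) * sqrt(hk$value))
  expect_identical(ci_hk$kind, "confidence")
  expect_identical(ci_hk$method, "HK")

  expect_error(confidence_interval(fit, hk, level = 1), "in \\(0, 1\\)")
})

test_that("intervals are nested in the level and degenerate at V = 0", {
  s <- toy3()
  fit <- fit_reml(s)
  ve <- variance_hk(s, fit)
  widths <- vapply(c(0.5, 0.8, 0.95, 0.99), function(lv) {
    interval_width(confidence_interval(fit, ve, lv))
  }, numeric(1))
  expect_true(all(diff(widths) > 0))

  flat <- study_set(rep(1, 3), se = c(0.1, 0.2, 0.3))
  ffit <- fit_reml(flat)
  ci0 <- confidence_interval(ffit, variance_hk(flat, ffit))
  expect_equal(ci0$lower, ci0$upper)
  expect_equal(ci0$lower, 1)
})

test_that("prediction intervals follow the t_{k-2} rule and widen over CIs", {
  set.seed(421)
  s <- rand_studies(6)
  fit <- fit_reml(s)
  for (m in c("N", "HK", "HK2", "SJ", "SJ2")) {
    ve <- meta_variance(m, s, fit)
    pi <- prediction_interval(fit, ve)
    expect_equal(interval_width(pi),
                 2 * stats::qt(0.975, 4) * sqrt(fit$tau2 + ve$value))
    if (fit$tau2 > 0) {
      expect_gt(interval_width(pi),
                interval_width(confidence_interval(fit, ve)))
    }
  }
  kr <- kr_adjust(s, fit)
  pik <- prediction_interval(fit, kr)
  expect_equal(interval_width(pik),
               2 * stats::qt(0.975, kr$df - 1) * sqrt(fit$tau2 + kr$value))
})

test_that("with tau2 = 0 the N prediction interval is the CI with t_{k-2}", {
  s <- study_set(c(0.2, 0.2, 0.2, 0.2), se = c(0.1, 0.15, 0.2, 0.12))
  fit <- fit_reml(s)
  expect_equal(fit$tau2, 0)
  pi <- prediction_interval(fit, variance_n(fit))
  expect_equal(interval_width(pi),
               2 * stats::qt(0.975, 2) * sqrt(fit$var_theta))
})

test_that("prediction intervals refuse impossible degrees of freedom", {
  two <- study_set(c(0.4, 0.6), se = c(0.2, 0.2))
  fit <- fit_reml(two)
  expect_error(prediction_interval(fit, variance_n(fit)), "k - 2")
  # equal weights at k = 2 give Kenward-Roger df = 1, so df - 1 = 0
  kr <- kr_adjust(two, fit)
  expect_equal(kr$df, 1)
  expect_error(prediction_interval(fit, kr), "df - 1")

  res <- meta_intervals(two)
  expect_true(all(is.na(res$pi_low)))
  expect_true(all(is.finite(res$ci_low)))
})

test_that("HK2 intervals are never narrower than HK or conventional ones", {
  set.seed(422)
  for (rep in 1:10) {
    s <- rand_studies(sample(3:9, 1))
    fit <- fit_reml(s)
    w_n <- interval_width(confidence_interval(fit, variance_n(fit)))
    w_hk <- interval_width(confidence_interval(fit, variance_hk(s, fit)))
    w_hk2 <- interval_width(confidence_interval(fit, variance_hk2(s, fit)))
    expect_gte(w_hk2, w_hk)
    expect_gte(w_hk2, w_n)
    if (variance_hk(s, fit)$q_factor >= 1) expect_equal(w_hk2, w_hk)
  }
})

test_that("all intervals are shift and scale equivariant", {
  set.seed(423)
  s <- rand_studies(7)
  shift <- 4.2
  scale <- 3.5
  res <- meta_intervals(s)
  res_sh <- meta_intervals(study_set(s$effects + shift, var = s$variances))
  res_sc <- meta_intervals(study_set(scale * s$effects,
                                     var = scale^2 * s$variances))
  for (col in c("estimate", "ci_low", "ci_high", "pi_low", "pi_high")) {
    expect_equal(res_sh[[col]], res[[col]] + shift, tolerance = 1e-6)
    expect_equal(res_sc[[col]], res[[col]] * scale, tolerance = 1e-6)
  }
})

test_that("meta_intervals reports one row per method with a shared fit", {
  res <- meta_intervals(dbp_meta("post"))
  expect_identical(res$method, meta_methods())
  expect_identical(names(res),
                   c("method", "estimate", "ci_low", "ci_high", "pi_low",
                     "pi_high", "tau2", "i2", "df_ci", "df_pi"))
  expect_equal(unique(res$estimate), attr(res, "fit")$theta)
  expect_equal(res$df_ci[res$method == "HK"], 6)
  expect_equal(res$df_pi[res$method == "SJ"], 5)
  expect_true(all(res$ci_low <= res$ci_high))
  expect_true(all(res$pi_low <= res$ci_low))

  sub <- meta_intervals(dbp_meta("post"), methods = c("HK", "KR"))
  expect_identical(sub$method, c("HK", "KR"))
  expect_error(meta_intervals(dbp_meta("post"), methods = "XX"),
               "unknown method")
})
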