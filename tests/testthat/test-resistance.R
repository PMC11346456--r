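test_that("censored-exponential log-likelihood matches its closed per-entry terms", {
  expect_equal(exponential_loglik(interval_set(10), 0.1), log(0.1) - 1)
  expect_equal(exponential_loglik(interval_set(40, TRUE), 0.05), -2)
  expect_error(exponential_loglik(interval_set(10), 0), "hazard")
  # unimodal in the hazard with the maximum at the closed-form MLE
  set.seed(11)
  iv <- random_intervals(25)
  grid <- seq(0.001, 1, by = 0.001)
  ll <- vapply(grid, function(h) exponential_loglik(iv, h), numeric(1))
  expect_true(all(is.finite(ll)))
  mle <- fit_exponential_mle(iv)$hazard
  expect_lt(abs(grid[which.max(ll)] - mle), 0.001)
  d <- diff(ll)
  expect_true(all(d[grid[-1] < mle - 0.002] > 0))
  expect_true(all(d[grid[-length(grid)] > mle + 0.002] < 0))
})

test_that("the closed-form MLE is events over total exposure", {
  fit <- fit_exponential_mle(interval_set(c(10, 20, 30)))
  expect_equal(fit$hazard, 1 / 20)
  expect_equal(fit$half_life, log(2) * 20, tolerance = 1e-12)
  cens <- fit_exponential_mle(interval_set(c(5, 15, 40),
                                           c(FALSE, FALSE, TRUE)))
  expect_equal(cens$hazard, 2 / 60)
  expect_equal(cens$half_life, log(2) * 30, tolerance = 1e-12)
  expect_equal(cens$n_events, 2L)
  expect_equal(cens$n_censored, 1L)
  # half_life * hazard = log 2 holds to numerical identity
  expect_equal(fit$half_life * fit$hazard, log(2), tolerance = 1e-12)
  expect_error(fit_exponential_mle(interval_set(c(10, 20), c(TRUE, TRUE))),
               "no uncensored")
  expect_error(fit_exponential_mle(interval_set(c(0, 0))), "zero total exposure")
})

test_that("numeric maximisation of the likelihood reproduces the closed form", {
  set.seed(12)
  for (rep in 1:10) {
    iv <- random_intervals(n = sample(5:60, 1), hazard = runif(1, 0.01, 0.3),
                           censor_at = runif(1, 10, 80))
    if (!any(!iv$censored)) next
    closed <- fit_exponential_mle(iv)$hazard
    numeric_mle <- optimize(function(h) exponential_loglik(iv, h),
                            interval = c(1e-6, 2), maximum = TRUE,
                            tol = 1e-10)$maximum
    expect_equal(numeric_mle, closed, tolerance = 1e-6)
  }
})

test_that("the censored MLE agrees with an independent survival-regression fit", {
  skip_if_not_installed("survival")
  set.seed(13)
  iv <- random_intervals(n = 80, hazard = log(2) / 15, censor_at = 45)
  sr <- survival::survreg(
    survival::Surv(iv$duration, !iv$censored) ~ 1, dist = "exponential")
  expect_equal(fit_exponential_mle(iv)$hazard, exp(-unname(coef(sr))),
               tolerance = 1e-6)
})

test_that("the binned Poisson fit converges to the unbinned MLE as bins shrink", {
  set.seed(14)
  iv <- interval_set(rexp(60, log(2) / 15))
  mle <- fit_exponential_mle(iv)$hazard
  err <- vapply(c(4, 2, 1, 0.5), function(w) {
    abs(fit_exponential_binned_poisson(iv, w)$hazard - mle)
  }, numeric(1))
  expect_lt(err[4], err[1] + 1e-8)      # shrinking bins, shrinking error
  expect_lt(err[4] / mle, 0.02)
})

test_that("binned and closed-form fits agree on large samples at moderate bins", {
  set.seed(15)
  iv <- interval_set(rexp(2000, log(2) / 15))
  binned <- fit_exponential_binned_poisson(iv, bin_width = 5)
  expect_equal(binned$method, "binned_poisson")
  expect_equal(binned$half_life, fit_exponential_mle(iv)$half_life,
               tolerance = 0.05)
})

test_that("a flat binned likelihood is reported as a degenerate-binning error", {
  expect_error(fit_exponential_binned_poisson(interval_set(3), bin_width = 10),
               "degenerate binning")
})

test_that("bootstrap intervals are seed-deterministic and bracket the estimate", {
  set.seed(16)
  iv <- random_intervals(n = 40, hazard = log(2) / 15, censor_at = 50)
  ci1 <- half_life_ci(iv, level = 0.95, n_boot = 400, seed = 99)
  ci2 <- half_life_ci(iv, level = 0.95, n_boot = 400, seed = 99)
  expect_identical(ci1, ci2)
  hl <- fit_exponential_mle(iv)$half_life
  expect_lt(ci1[["lower"]], hl)
  expect_gt(ci1[["upper"]], hl)
  expect_lt(ci1[["lower"]], ci1[["upper"]])
  expect_error(half_life_ci(iv, n_boot = 100), "seed.*required")
  # confint method delegates to the same bootstrap
  fit <- fit_exponential_mle(iv)
  expect_equal(unname(confint(fit, n_boot = 400, seed = 99)), unname(ci1))
})

test_that("bootstrap interval width shrinks like one over root n", {
  set.seed(17)
  small <- interval_set(rexp(500, log(2) / 15))
  large <- interval_set(rexp(2000, log(2) / 15))
  w_small <- diff(half_life_ci(small, n_boot = 600, seed = 5))
  w_large <- diff(half_life_ci(large, n_boot = 600, seed = 5))
  expect_equal(unname(w_small / w_large), 2, tolerance = 0.2)
})

test_that("survival curve obeys its defining identities", {
  fit <- fit_exponential_mle(interval_set(c(10, 20, 30)))
  expect_equal(survival_curve(fit, 0), 1)
  expect_equal(survival_curve(fit, fit$half_life), 0.5, tolerance = 1e-12)
  grid <- seq(0, 120, by = 0.5)
  expect_true(all(diff(survival_curve(fit, grid)) < 0))
  expect_error(survival_curve(fit, c(-1, 3)), "non-negative")
  expect_equal(predict(fit, grid), survival_curve(fit, grid))
})

test_that("dropping censored exposure never decreases the fitted hazard", {
  set.seed(18)
  for (rep in 1:20) {
    iv <- random_intervals(n = sample(10:50, 1), hazard = runif(1, 0.02, 0.2),
                           censor_at = runif(1, 10, 60))
    if (!any(iv$censored) || !any(!iv$censored)) next
    full <- fit_exponential_mle(iv)$hazard
    events_only <- fit_exponential_mle(iv[!iv$censored, ])$hazard
    expect_gte(events_only, full)
  }
})

test_that("the hazard estimate is nearly unbiased at moderate sample size", {
  true_hazard <- log(2) / 15
  set.seed(19)
  rel_bias <- vapply(1:20, function(s) {
    iv <- interval_set(rexp(500, true_hazard))
    fit_exponential_mle(iv)$hazard / true_hazard - 1
  }, numeric(1))
  expect_lt(abs(median(rel_bias)), 0.05)
})
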