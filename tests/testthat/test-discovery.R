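test_that("the coupon-collector expectation matches exhaustive enumeration", {
  expect_equal(expected_distinct_given_draws(3, 2), 5 / 3, tolerance = 1e-12)
  for (k in 1:5) {
    for (m in 0:6) {
      expect_equal(expected_distinct_given_draws(k, m),
                   enum_expected_distinct(k, m), tolerance = 1e-12)
    }
  }
  expect_equal(expected_distinct_given_draws(1, c(1, 5, 50)), c(1, 1, 1))
  expect_equal(expected_distinct_given_draws(5, 1000), 5, tolerance = 1e-9)
  # strictly increasing in the number of draws
  expect_true(all(diff(expected_distinct_given_draws(7, 0:50)) > 0))
  expect_error(expected_distinct_given_draws(0, 3), "k")
  expect_error(expected_distinct_given_draws(3, 2.5), "m")
})

test_that("the Poisson-draw marginal matches the mixture over fixed draw counts", {
  p <- discovery_params(k = 30, n = 1.5, t_lag = 28, t0 = 1900)
  expect_equal(expected_discoveries(1950, p), 30 * (1 - exp(-1.1)))
  expect_equal(expected_discoveries(c(1900, 1928), p), c(0, 0))
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(2:50, 1)
    n <- runif(1, 0.2, 5)
    tau <- runif(1, 1, 60)
    m_max <- qpois(1 - 1e-14, n * tau) + 50
    mixture <- sum(dpois(0:m_max, n * tau) *
                     expected_distinct_given_draws(k, 0:m_max))
    pk <- discovery_params(k, n, 0, 0)
    expect_equal(expected_discoveries(tau, pk), mixture, tolerance = 1e-9)
  }
})

test_that("the expectation saturates below k and linearises for large pools", {
  p <- discovery_params(25, 2, 10, 1900)
  tt <- seq(1900, 2100, by = 0.5)
  ED <- expected_discoveries(tt, p)
  expect_true(all(ED <= 25))
  expect_true(all(diff(ED) >= 0))
  expect_lt(max(ED), 25)   # never reaches the pool at finite time
  big <- discovery_params(1e6, 1.5, 0, 0)
  expect_equal(expected_discoveries(40, big), 1.5 * 40, tolerance = 1e-3)
})

test_that("the yearly-count likelihood matches a term-by-term independent computation", {
  p <- discovery_params(k = 10, n = 1, t_lag = 2, t0 = 2000)
  counts <- yearly_counts(c(0, 0, 1, 2, 1), 2000)
  # hand-built means: increments of k(1 - exp(-n tau / k)) over [y, y+1)
  tau <- function(t) pmax(0, t - 2002)
  mu <- 10 * (exp(-tau(2000:2004) / 10) - exp(-tau(2001:2005) / 10))
  expect_equal(discovery_loglik(counts, p),
               sum(dpois(c(0, 0, 1, 2, 1), mu, log = TRUE)))
  # empty window entirely inside the lag has likelihood exactly zero
  expect_equal(discovery_loglik(yearly_counts(c(0, 0), 2000),
                                discovery_params(10, 1, 30, 2000)), 0)
  # an observed discovery during the lag phase is impossible, not an error
  expect_equal(discovery_loglik(yearly_counts(c(1, 0, 0), 2000),
                                discovery_params(10, 1, 30, 2000)), -Inf)
})

test_that("fitted yearly increments telescope to the cumulative expectation", {
  p <- discovery_params(k = 30, n = 1.5, t_lag = 28, t0 = 1900)
  mu <- round(expected_discoveries(1901:1990, p) -
                expected_discoveries(1900:1989, p))
  fit <- fit_discovery(yearly_counts(mu, 1900), k_max = 100, t_lag_max = 60)
  inc <- predict(fit, type = "increment")
  expect_equal(sum(inc),
               expected_discoveries(1990, fit$params) -
                 expected_discoveries(1900, fit$params),
               tolerance = 1e-10)
})

test_that("noise-free counts recover the generating parameters", {
  p <- discovery_params(k = 30, n = 1.5, t_lag = 28, t0 = 1900)
  # integerise the noise-free curve mass-preservingly: rounding the yearly
  # means directly would silently delete ~30% of the classes
  mu <- diff(round(expected_discoveries(1900:1990, p)))
  fit <- fit_discovery(yearly_counts(mu, 1900), k_max = 200,
                       t_lag_max = 60)
  expect_lte(abs(fit$params$t_lag - 28), 3)
  expect_lt(abs(fit$params$n - 1.5) / 1.5, 0.2)
  expect_true(fit$converged)
  # deterministic: identical reruns give bit-identical results
  fit2 <- fit_discovery(yearly_counts(mu, 1900), k_max = 200,
                        t_lag_max = 60)
  expect_identical(coef(fit), coef(fit2))
})

test_that("the grid-profile maximiser matches a brute-force dense scan", {
  p <- discovery_params(k = 8, n = 1, t_lag = 5, t0 = 0)
  set.seed(22)
  mu <- expected_discoveries(1:40, p) - expected_discoveries(0:39, p)
  counts <- yearly_counts(rpois(40, mu), 0)
  fit <- fit_discovery(counts, k_max = 25, t_lag_max = 15, t0 = 0)
  brute <- -Inf
  for (k in sum(counts$counts):25) {
    for (t_lag in 0:15) {
      for (n in seq(0.05, 4, by = 0.005)) {
        ll <- discovery_loglik(counts, discovery_params(k, n, t_lag, 0))
        if (ll > brute) brute <- ll
      }
    }
  }
  expect_gte(fit$loglik, brute - 1e-6)
})

test_that("degenerate or infeasible inputs are rejected", {
  expect_error(fit_discovery(yearly_counts(c(0, 5, 0), 1950), k_max = 20),
               ">= 2 distinct years")
  expect_error(fit_discovery(yearly_counts(c(1, 0, 0, 1), 1950), k_max = 1),
               "below the 2 observed classes")
  # pool size can never undercut what was observed
  set.seed(23)
  counts <- yearly_counts(rpois(30, 0.8), 1950)
  fit <- fit_discovery(counts, k_max = 60)
  expect_gte(fit$params$k, sum(counts$counts))
})
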