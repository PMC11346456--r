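# Independent oracles and fixtures used across the suite.  Each oracle is a
# separate derivation from the one used by the package code path it checks.

# Coupon-collector expectation by exhaustive enumeration of all k^m equally
# likely draw sequences (feasible for k <= 5, m <= 6).
enum_expected_distinct <- function(k, m) {
  if (m == 0L) return(0)
  grids <- expand.grid(rep(list(seq_len(k)), m))
  mean(apply(grids, 1L, function(row) length(unique(row))))
}

# Closed-form convolution of the discovery intensity with the per-class
# exponential CDF: E[R(t)] = D(t) - n (e^{-r tau} - e^{-lambda tau})/(lambda - r),
# r = n/k, tau = max(0, t - t0 - t_lag).  Derived analytically, independent of
# the quadrature the package uses.
closed_form_ER <- function(t, p, half_life, lambda = log(2) / half_life) {
  r <- p$n / p$k
  tau <- pmax(0, t - p$t0 - p$t_lag)
  D <- p$k * (1 - exp(-r * tau))
  if (abs(lambda - r) < 1e-10) {
    D - p$n * tau * exp(-r * tau)
  } else {
    D - p$n * (exp(-r * tau) - exp(-lambda * tau)) / (lambda - r)
  }
}

# The study conditions used throughout: pool of 30 classes sampled at 1.5
# draws/year after a 28-year lag from 1900, clinical half-life 15 years,
# observed to 2020.
study_config <- function(seed, k = 30, n = 1.5, t_lag = 28, t0 = 1900,
                         half_life = 15, horizon = 2020,
                         observation = horizon, use_delay = 8) {
  simulation_config(discovery_params(k, n, t_lag, t0),
                    half_life = half_life, use_delay_mean = use_delay,
                    horizon_year = horizon, observation_year = observation,
                    seed = seed)
}

# Random censored interval sets for property tests (caller controls the RNG).
random_intervals <- function(n = 30, hazard = 0.05, censor_at = 40) {
  d <- stats::rexp(n, hazard)
  cens <- d > censor_at
  interval_set(ifelse(cens, censor_at, d), cens)
}
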