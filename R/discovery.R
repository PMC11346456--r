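#' Discovery-process parameters
#'
#' Parameters of the coupon-collector model of antibacterial class
#' discovery: draws (screening hits) arrive as a homogeneous Poisson
#' process at rate `n` per year starting `t_lag` years after the origin
#' year `t0`, and each draw lands uniformly on one of `k` classes.  A class
#' is discovered at its first draw, so repeated draws on common classes
#' are rediscoveries.
#'
#' @param k pool size: number of discoverable classes, integer `>= 1`.
#' @param n sampling rate, draws per year, `> 0`.
#' @param t_lag lag phase in years before sampling starts, `>= 0`.
#' @param t0 origin calendar year.
#' @return an object of class `discovery_params`.
#' @export
discovery_params <- function(k, n, t_lag, t0) {
  check_scalar(k, "k", lower = 1, integer = TRUE)
  check_scalar(n, "n", lower = 0, allow_lower = FALSE)
  check_scalar(t_lag, "t_lag", lower = 0)
  check_scalar(t0, "t0")
  structure(list(k = as.integer(k), n = n, t_lag = t_lag, t0 = t0),
            class = "discovery_params")
}

#' @export
print.discovery_params <- function(x, ...) {
  cat(sprintf(
    "Discovery parameters: k = %d classes, n = %g draws/year, t_lag = %g years from t0 = %g\n",
    x$k, x$n, x$t_lag, x$t0))
  invisible(x)
}

#' Expected distinct classes after a fixed number of draws
#'
#' The coupon-collector expectation: after `m` uniform draws with
#' replacement from `k` classes, the expected number of distinct classes
#' seen is `k * (1 - (1 - 1/k)^m)`.
#'
#' @param k pool size, integer `>= 1`.
#' @param m number of draws, integer `>= 0`; may be a vector.
#' @return expected distinct classes, same length as `m`.
#' @export
expected_distinct_given_draws <- function(k, m) {
  check_scalar(k, "k", lower = 1, integer = TRUE)
  if (any(!is.finite(m) | m < 0 | m != trunc(m))) {
    stop("`m` must contain non-negative integers", call. = FALSE)
  }
  k * (1 - (1 - 1 / k)^m)
}

#' Expected number of discovered classes at a calendar time
#'
#' With draws arriving as a Poisson process of rate `n` per year after the
#' lag, the draw count by effective time `tau = max(0, t - t0 - t_lag)` is
#' Poisson(`n*tau`), and averaging the fixed-draw coupon-collector
#' expectation over it gives the exact marginal
#' `E[D(t)] = k * (1 - exp(-n * tau / k))`: zero through the lag phase,
#' non-decreasing, and bounded above by the pool size `k`.
#'
#' @param t calendar time(s), may be a vector.
#' @param params a [discovery_params()].
#' @return `E[D(t)]`, same length as `t`.
#' @export
expected_discoveries <- function(t, params) {
  stopifnot(inherits(params, "discovery_params"))
  tau <- pmax(0, t - params$t0 - params$t_lag)
  params$k * (1 - exp(-params$n * tau / params$k))
}

# Vectorised Poisson increment log-likelihood used by the fitters: counts c_y
# against means mu_y; years with mu_y = 0 but c_y > 0 give -Inf.
poisson_increment_loglik <- function(counts, mu, lfact = lfactorial(counts)) {
  pos <- counts > 0L
  if (any(pos & mu <= 0)) return(-Inf)
  sum(counts[pos] * log(mu[pos])) - sum(mu) - sum(lfact)
}

#' Poisson log-likelihood of yearly new-class counts
#'
#' Treats the count of first discoveries in calendar year y as Poisson with
#' mean `mu_y = E[D(y+1)] - E[D(y)]` under [expected_discoveries()] (years
#' are half-open intervals `[y, y+1)`).  A positive count in a year with
#' zero model mean (e.g. during the lag phase) gives `-Inf`, not an error.
#'
#' @param counts a [yearly_counts()] of first discoveries.
#' @param params a [discovery_params()].
#' @return the log-likelihood, possibly `-Inf`.
#' @export
discovery_loglik <- function(counts, params) {
  stopifnot(inherits(counts, "yearly_counts"))
  ys <- counts$start_year + seq_along(counts$counts) - 1L
  mu <- expected_discoveries(ys + 1, params) - expected_discoveries(ys, params)
  poisson_increment_loglik(counts$counts, mu)
}

#' Fit the coupon-collector discovery model to yearly counts
#'
#' Maximises the Poisson increment likelihood over an integer grid of pool
#' sizes `k` (from the observed number of classes up to `k_max`) and lag
#' phases `t_lag` (0 to `t_lag_max` years), with the sampling rate `n`
#' profiled out by bounded scalar optimisation (tolerance 1e-8) at each
#' grid point.  Deterministic; ties broken toward the smallest `k`, then
#' the smallest `t_lag`.
#'
#' @param counts a [yearly_counts()] with at least 2 events over at least 2
#'   distinct years.
#' @param k_max largest pool size searched (default 200).
#' @param t_lag_max largest lag searched, years (default 60).
#' @param t0 origin year the lag is measured from; defaults to the first
#'   year of the counts window.
#' @param n_max upper bound of the sampling-rate search, draws/year
#'   (default 50).
#' @return an object of class `discovery_fit`: `params`
#'   ([discovery_params()]), `loglik`, `searched`, `converged`, and the
#'   counts.
#' @examples
#' p <- discovery_params(k = 12, n = 0.8, t_lag = 10, t0 = 1900)
#' mu <- expected_discoveries(1901:1980, p) - expected_discoveries(1900:1979, p)
#' fit <- fit_discovery(yearly_counts(round(mu), 1900), k_max = 40)
#' coef(fit)
#' @export
fit_discovery <- function(counts, k_max = 200, t_lag_max = 60, t0 = NULL,
                          n_max = 50) {
  stopifnot(inherits(counts, "yearly_counts"))
  check_scalar(k_max, "k_max", lower = 1, integer = TRUE)
  check_scalar(t_lag_max, "t_lag_max", lower = 0, integer = TRUE)
  c_y <- counts$counts
  total <- sum(c_y)
  if (total < 2L || sum(c_y > 0L) < 2L) {
    stop("need >= 2 discoveries over >= 2 distinct years to fit", call. = FALSE)
  }
  t0 <- t0 %||% counts$start_year
  check_scalar(t0, "t0")
  if (k_max < total) {
    stop(sprintf("k_max = %d is below the %d observed classes", k_max, total),
         call. = FALSE)
  }
  ys <- counts$start_year + seq_along(c_y) - 1L
  lfact <- lfactorial(c_y)
  first_pos <- ys[which(c_y > 0L)[1L]]
  # counts in year y need t0 + t_lag < y + 1, so lags beyond the first
  # positive year are infeasible and skipped.
  lag_grid <- 0:t_lag_max
  lag_grid <- lag_grid[t0 + lag_grid <= first_pos]
  if (length(lag_grid) == 0L) {
    stop("no feasible lag: t0 is later than the first observed discovery",
         call. = FALSE)
  }
  best <- list(ll = -Inf, k = NA_integer_, t_lag = NA_real_, n = NA_real_)
  for (t_lag in lag_grid) {
    a <- t0 + t_lag
    tau_lo <- pmax(0, ys - a)
    tau_hi <- pmax(0, ys + 1 - a)
    for (k in total:k_max) {
      ll_n <- function(n) {
        mu <- k * (exp(-n * tau_lo / k) - exp(-n * tau_hi / k))
        poisson_increment_loglik(c_y, mu, lfact)
      }
      opt <- stats::optimize(ll_n, interval = c(1e-8, n_max),
                             maximum = TRUE, tol = 1e-8)
      if (opt$objective > best$ll) {
        best <- list(ll = opt$objective, k = k, t_lag = t_lag, n = opt$maximum)
      }
    }
  }
  if (!is.finite(best$ll)) {
    stop("no parameter combination achieved a finite likelihood", call. = FALSE)
  }
  structure(list(
    params = discovery_params(best$k, best$n, best$t_lag, t0),
    loglik = best$ll,
    searched = sprintf(
      "k in [%d, %d] (integer), t_lag in [0, %d] (integer, %d feasible), n in (0, %g] (tol 1e-8)",
      total, k_max, t_lag_max, length(lag_grid), n_max),
    converged = TRUE,
    counts = counts), class = "discovery_fit")
}

#' @export
print.discovery_fit <- function(x, digits = 4, ...) {
  cat("Coupon-collector discovery fit (Poisson ML on yearly counts)\n")
  cat(sprintf("  pool size k:      %d classes\n", x$params$k))
  cat(sprintf("  sampling rate n:  %s draws/year\n",
              format(x$params$n, digits = digits)))
  cat(sprintf("  lag phase t_lag:  %g years (origin t0 = %g)\n",
              x$params$t_lag, x$params$t0))
  cat(sprintf("  log-likelihood:   %s   (%s)\n",
              format(x$loglik, digits = digits),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.discovery_fit <- function(object, ...) {
  with(object$params, c(k = k, n = n, t_lag = t_lag, t0 = t0))
}

#' @export
logLik.discovery_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = length(object$counts$counts),
            class = "logLik")
}

#' @export
predict.discovery_fit <- function(object, years = NULL,
                                  type = c("cumulative", "increment"), ...) {
  type <- match.arg(type)
  if (is.null(years)) {
    years <- object$counts$start_year + seq_along(object$counts$counts) - 1L
  }
  if (type == "cumulative") {
    expected_discoveries(years, object$params)
  } else {
    expected_discoveries(years + 1, object$params) -
      expected_discoveries(years, object$params)
  }
}

#' @export
fitted.discovery_fit <- function(object, ...) {
  predict.discovery_fit(object, type = "increment")
}

#' @export
residuals.discovery_fit <- function(object, ...) {
  # Pearson residuals of the yearly counts against the fitted Poisson means.
  mu <- fitted.discovery_fit(object)
  (object$counts$counts - mu) / sqrt(pmax(mu, .Machine$double.eps))
}
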