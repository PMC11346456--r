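#' Censored-exponential log-likelihood of discovery-to-resistance times
#'
#' Under a constant per-class hazard `hazard` (per year), an uncensored
#' interval of length d contributes `log(hazard) - hazard * d` and a
#' right-censored interval contributes the survival term `-hazard * d`.
#'
#' @param intervals an [interval_set()] (any data frame with `duration` and
#'   `censored` columns).
#' @param hazard resistance-detection rate per year, `> 0`.
#' @return the log-likelihood (finite for any positive hazard and finite
#'   durations).
#' @export
exponential_loglik <- function(intervals, hazard) {
  check_scalar(hazard, "hazard", lower = 0, allow_lower = FALSE)
  sum(!intervals$censored) * log(hazard) - hazard * sum(intervals$duration)
}

new_exp_fit <- function(hazard, loglik, n_events, n_censored, method,
                        intervals, extra = list()) {
  structure(c(list(hazard = hazard,
                   half_life = log(2) / hazard,
                   loglik = loglik,
                   n_events = n_events,
                   n_censored = n_censored,
                   ci_half_life = NULL,
                   method = method,
                   intervals = intervals), extra),
            class = "exp_fit")
}

#' Fit the exponential time-to-resistance model by maximum likelihood
#'
#' The censored-exponential maximum-likelihood estimate is the closed form
#' `hazard = n_events / total exposure`, where total exposure is the sum of
#' all durations, censored classes contributing their observation time.
#' The clinical half-life is the median of the fitted distribution,
#' `log(2) / hazard`.
#'
#' @param intervals an [interval_set()] with at least one uncensored event
#'   and positive total exposure.
#' @return an object of class `exp_fit` with components `hazard`,
#'   `half_life`, `loglik`, `n_events`, `n_censored`, `method`
#'   (`"closed_form_mle"`), and the data.
#' @seealso [fit_exponential_binned_poisson()], [half_life_ci()],
#'   [survival_curve()]
#' @examples
#' iv <- interval_set(c(10, 20, 30))
#' fit <- fit_exponential_mle(iv)
#' coef(fit)            # hazard 0.05, half-life ~13.9 years
#' @export
fit_exponential_mle <- function(intervals) {
  n_events <- sum(!intervals$censored)
  exposure <- sum(intervals$duration)
  if (n_events == 0L) {
    stop("cannot fit: no uncensored resistance events", call. = FALSE)
  }
  if (exposure <= 0) {
    stop("cannot fit: zero total exposure (all durations are zero)",
         call. = FALSE)
  }
  hazard <- n_events / exposure
  new_exp_fit(hazard, exponential_loglik(intervals, hazard),
              n_events, sum(intervals$censored),
              "closed_form_mle", intervals)
}

#' Fit the exponential model by Poisson maximum likelihood on binned counts
#'
#' Histograms the uncensored durations into half-open bins
#' `[i*w, (i+1)*w)` spanning zero through the last non-empty bin (plus the
#' empty open tail beyond it, so the expected masses total the sample) and
#' treats the bin counts as independent Poisson with mean
#' `mu_i = N * (exp(-hazard*a_i) - exp(-hazard*b_i))`, `N` the event count.
#' This is the histogram-overlay fit of the resistance-time distribution;
#' it converges to the unbinned maximum-likelihood estimate as the bin
#' width shrinks.
#'
#' @param intervals an [interval_set()] with at least one uncensored event.
#'   Censored entries are ignored by this method.
#' @param bin_width bin width w in years, `> 0` (default 5).
#' @return an `exp_fit` with `method = "binned_poisson"`.
#' @export
fit_exponential_binned_poisson <- function(intervals, bin_width = 5) {
  check_scalar(bin_width, "bin_width", lower = 0, allow_lower = FALSE)
  d <- intervals$duration[!intervals$censored]
  if (length(d) == 0L) {
    stop("cannot fit: no uncensored resistance events", call. = FALSE)
  }
  n_bins <- floor(max(d) / bin_width) + 1L
  if (n_bins < 2L) {
    stop(sprintf(paste0(
      "degenerate binning: all %d event(s) fall in the first bin [0, %g); ",
      "the binned Poisson likelihood is flat in the hazard -- ",
      "use a smaller bin_width or fit_exponential_mle()"),
      length(d), bin_width), call. = FALSE)
  }
  counts <- tabulate(pmin(floor(d / bin_width), n_bins - 1L) + 1L, n_bins)
  # implicit empty tail bin [B, Inf) so the expected masses total N: the
  # multinomial reading whose small-bin limit is the unbinned MLE
  counts <- c(counts, 0L)
  a <- c((seq_len(n_bins) - 1L) * bin_width, n_bins * bin_width)
  b <- c(a[-length(a)] + bin_width, Inf)
  N <- length(d)
  nll_const <- sum(lfactorial(counts))
  binned_ll <- function(log_hazard) {
    h <- exp(log_hazard)
    mu <- N * (exp(-h * a) - exp(-h * b))
    pos <- counts > 0L
    if (any(pos & mu <= 0)) return(-Inf)
    sum(counts[pos] * log(mu[pos])) - sum(mu) - nll_const
  }
  opt <- stats::optimize(binned_ll, interval = log(c(1e-8, 1e3)),
                         maximum = TRUE, tol = 1e-10)
  hazard <- exp(opt$maximum)
  fit <- new_exp_fit(hazard, opt$objective, N, sum(intervals$censored),
                     "binned_poisson", intervals,
                     extra = list(bin_width = bin_width,
                                  bin_counts = counts))
  fit
}

#' Percentile-bootstrap confidence interval for the clinical half-life
#'
#' Resamples interval-set entries with replacement (censoring flags travel
#' with their entries), refits the closed-form censored-exponential
#' maximum-likelihood estimate on each replicate, and returns percentile
#' quantiles of the replicate half-lives.  Replicates with no events or no
#' exposure are redrawn (at most 100 retries each).
#'
#' @param intervals an [interval_set()] with at least two events.
#' @param level confidence level in (0, 1); default 0.95.
#' @param n_boot number of bootstrap replicates; default 1000.
#' @param seed integer seed; results are deterministic given the seed and
#'   the caller's RNG state is untouched.
#' @return named numeric `c(lower, upper)` in years.
#' @export
half_life_ci <- function(intervals, level = 0.95, n_boot = 1000, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  check_scalar(level, "level", lower = 0, upper = 1, allow_lower = FALSE)
  if (level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  check_scalar(n_boot, "n_boot", lower = 1, integer = TRUE)
  n <- nrow(intervals)
  if (sum(!intervals$censored) < 2L) {
    stop("need at least two uncensored events for a bootstrap interval",
         call. = FALSE)
  }
  dur <- intervals$duration
  cens <- intervals$censored
  hl <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      for (try in seq_len(100L)) {
        idx <- sample.int(n, n, replace = TRUE)
        ev <- sum(!cens[idx])
        expo <- sum(dur[idx])
        if (ev > 0L && expo > 0) return(log(2) * expo / ev)
      }
      stop("bootstrap replicate had no events after 100 redraws",
           call. = FALSE)
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  out <- stats::quantile(hl, c(alpha, 1 - alpha), names = FALSE)
  names(out) <- c("lower", "upper")
  out
}

#' Exponential survival curve
#'
#' Probability that a class discovered at time zero still has no detected
#' resistance after `grid` years: `S(t) = exp(-hazard * t)`.
#'
#' @param fit an `exp_fit`, or a single positive hazard.
#' @param grid non-negative times in years.
#' @return numeric vector of survival probabilities.
#' @export
survival_curve <- function(fit, grid) {
  hazard <- if (inherits(fit, "exp_fit")) fit$hazard else fit
  check_scalar(hazard, "hazard", lower = 0, allow_lower = FALSE)
  if (any(!is.finite(grid) | grid < 0)) {
    stop("`grid` must be non-negative and finite", call. = FALSE)
  }
  exp(-hazard * grid)
}

#' @export
print.exp_fit <- function(x, digits = 4, ...) {
  cat("Exponential time-to-resistance fit (",
      if (x$method == "binned_poisson") "binned Poisson ML" else "censored ML",
      ")\n", sep = "")
  cat(sprintf("  hazard:    %s per year\n", format(x$hazard, digits = digits)))
  cat(sprintf("  half-life: %s years\n", format(x$half_life, digits = digits)))
  if (!is.null(x$ci_half_life)) {
    cat(sprintf("  half-life CI: [%s, %s] years\n",
                format(x$ci_half_life[1], digits = digits),
                format(x$ci_half_life[2], digits = digits)))
  }
  cat(sprintf("  events: %d   censored: %d   log-likelihood: %s\n",
              x$n_events, x$n_censored, format(x$loglik, digits = digits)))
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) {
  c(hazard = object$hazard, half_life = object$half_life)
}

#' @export
logLik.exp_fit <- function(object, ...) {
  structure(object$loglik, df = 1L, nobs = object$n_events + object$n_censored,
            class = "logLik")
}

#' @export
confint.exp_fit <- function(object, parm = "half_life", level = 0.95,
                            n_boot = 1000, seed, ...) {
  ci <- half_life_ci(object$intervals, level = level, n_boot = n_boot,
                     seed = seed)
  if (identical(parm, "hazard")) ci <- rev(log(2) / ci)
  names(ci) <- c("lower", "upper")
  ci
}

#' @export
predict.exp_fit <- function(object, times, ...) {
  survival_curve(object, times)
}

#' @export
summary.exp_fit <- function(object, ...) {
  structure(object, class = c("summary.exp_fit", "exp_fit"))
}

#' @export
print.summary.exp_fit <- function(x, ...) {
  print.exp_fit(x, ...)
  ev <- x$intervals$duration[!x$intervals$censored]
  if (length(ev)) {
    cat("  observed event durations (years):\n")
    print(summary(ev))
  }
  invisible(x)
}

#' @export
residuals.exp_fit <- function(object, ...) {
  # Cox-Snell residuals: hazard * duration; censored entries keep their flag.
  r <- object$hazard * object$intervals$duration
  attr(r, "censored") <- object$intervals$censored
  r
}

#' @export
simulate.exp_fit <- function(object, nsim = 1, seed, ...) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  n <- nrow(object$intervals)
  with_seed(seed, {
    replicate(nsim, stats::rexp(n, rate = object$hazard), simplify = FALSE)
  })
}
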