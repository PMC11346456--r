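resolve_hazard <- function(half_life, rate_definition) {
  check_scalar(half_life, "half_life", lower = 0, allow_lower = FALSE)
  switch(rate_definition,
         log2_over_half_life = log(2) / half_life,
         one_over_half_life = 1 / half_life,
         stop("unknown rate_definition", call. = FALSE))
}

#' Expected number of classes with detected resistance
#'
#' Two readings of "resistance grows exponentially with rate 1/half-life"
#' are provided:
#'
#' * `per_class_hazard` (default, mechanistic): each discovered class
#'   acquires detected resistance after an exponential waiting time with
#'   median `half_life`, so
#'   `E[R(t)] = integral of D'(s) * (1 - exp(-lambda (t - s))) ds` over
#'   discovery times s, evaluated by adaptive quadrature (absolute
#'   tolerance 1e-8).  This is consistent with the fitted per-class
#'   exponential and is bounded by `E[D(t)]`.
#' * `literal_exponential`: the count itself grows geometrically,
#'   `R(t) = min(E[D(t)], exp((t - t_onset) / half_life))`, with an onset
#'   year `t_onset` (default: start of discovery, `t0 + t_lag`).  Provided
#'   because an unanchored exponential-growth curve needs an amplitude
#'   convention; capping by D keeps it interpretable.
#'
#' By default the per-class hazard is `log(2) / half_life` (the exponential
#' median convention); `rate_definition = "one_over_half_life"` selects the
#' literal reciprocal rate.
#'
#' @param t calendar time(s).
#' @param dparams a [discovery_params()].
#' @param half_life clinical half-life in years, `> 0`.
#' @param mode `"per_class_hazard"` or `"literal_exponential"`.
#' @param t_onset onset year for the literal mode.
#' @param rate_definition how the per-class hazard is derived from the
#'   half-life.
#' @return `E[R(t)]`, same length as `t`; zero before any discovery and
#'   non-decreasing.
#' @export
expected_resistant <- function(t, dparams, half_life,
                               mode = c("per_class_hazard",
                                        "literal_exponential"),
                               t_onset = NULL,
                               rate_definition = c("log2_over_half_life",
                                                   "one_over_half_life")) {
  stopifnot(inherits(dparams, "discovery_params"))
  mode <- match.arg(mode)
  rate_definition <- match.arg(rate_definition)
  lambda <- resolve_hazard(half_life, rate_definition)
  a <- dparams$t0 + dparams$t_lag
  if (mode == "literal_exponential") {
    t_onset <- t_onset %||% a
    growth <- exp((t - t_onset) / half_life)
    return(pmin(expected_discoveries(t, dparams), growth))
  }
  k <- dparams$k
  n <- dparams$n
  vapply(t, function(ti) {
    if (ti <= a) return(0)
    q <- stats::integrate(
      function(s) n * exp(-n * (s - a) / k) * (1 - exp(-lambda * (ti - s))),
      lower = a, upper = ti, abs.tol = 1e-8, rel.tol = 1e-10,
      subdivisions = 200L)
    min(q$value, expected_discoveries(ti, dparams))
  }, numeric(1))
}

#' Curves of discovered, resistant, and not-yet-resistant classes
#'
#' Evaluates `E[D(t)]`, `E[R(t)]` and their difference
#' `U(t) = E[D(t)] - E[R(t)]` -- the expected number of classes whose
#' resistance has not yet been detected -- on a calendar-year grid.  U
#' rises while discovery outpaces resistance accrual and declines once the
#' pool is depleted; the identity `U = D - R` holds exactly at every grid
#' point, and `0 <= R <= D <= k` throughout.
#'
#' @inheritParams expected_resistant
#' @param years calendar-year grid.
#' @return a data frame of class `dynamics_curve` with columns `year`,
#'   `discovered`, `resistant`, `undetected`; the mode and parameters are
#'   attached as attributes.
#' @export
undetected_curve <- function(dparams, half_life, years,
                             mode = c("per_class_hazard",
                                      "literal_exponential"),
                             t_onset = NULL,
                             rate_definition = c("log2_over_half_life",
                                                 "one_over_half_life")) {
  mode <- match.arg(mode)
  rate_definition <- match.arg(rate_definition)
  if (any(!is.finite(years))) stop("`years` must be finite", call. = FALSE)
  D <- expected_discoveries(years, dparams)
  R <- expected_resistant(years, dparams, half_life, mode = mode,
                          t_onset = t_onset,
                          rate_definition = rate_definition)
  R <- pmin(R, D)
  out <- data.frame(year = years, discovered = D, resistant = R,
                    undetected = D - R)
  attr(out, "mode") <- mode
  attr(out, "params") <- dparams
  attr(out, "half_life") <- half_life
  class(out) <- c("dynamics_curve", "data.frame")
  out
}

#' @export
print.dynamics_curve <- function(x, ...) {
  cat(sprintf(
    "Dynamics curve (%s): %d years [%g, %g], half-life %g years\n",
    attr(x, "mode"), nrow(x), min(x$year), max(x$year),
    attr(x, "half_life")))
  peak <- x[which.max(x$undetected), ]
  cat(sprintf(
    "  peak not-yet-resistant repertoire: %.2f classes in %g\n",
    peak$undetected, peak$year))
  invisible(x)
}

#' @export
plot.dynamics_curve <- function(x, ...) {
  graphics::matplot(x$year, cbind(x$discovered, x$resistant, x$undetected),
                    type = "l", lty = 1, lwd = 2,
                    col = c("grey40", "darkorange", "steelblue"),
                    xlab = "year", ylab = "classes", ...)
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("grey40", "darkorange", "steelblue"),
                   legend = c("discovered D", "resistant R",
                              "not yet resistant U = D - R"))
  invisible(x)
}

#' Fit the resistance-detection half-life from yearly counts
#'
#' Stagewise Poisson maximum likelihood: with the discovery parameters held
#' fixed at a previous [fit_discovery()], maximises
#' `sum_y [c_y log nu_y - nu_y - log(c_y!)]` over the half-life, where
#' `nu_y = E[R(y+1)] - E[R(y)]` under [expected_resistant()] and `c_y` are
#' the classes whose resistance was first detected in year y.  Bounded
#' scalar search on the half-life (tolerance 1e-8); deterministic.
#'
#' @param resistance_counts a [yearly_counts()] of first resistance
#'   detections, not all zero.
#' @param dfit a `discovery_fit` (or a [discovery_params()]).
#' @param mode,t_onset,rate_definition passed to [expected_resistant()].
#' @param half_life_max upper search bound in years (default 200).
#' @return an object of class `resistance_detection_fit`: `half_life`,
#'   `hazard`, `loglik`, `mode`, the counts and discovery parameters.
#' @export
fit_resistance_detection <- function(resistance_counts, dfit,
                                     mode = c("per_class_hazard",
                                              "literal_exponential"),
                                     t_onset = NULL,
                                     rate_definition = c("log2_over_half_life",
                                                         "one_over_half_life"),
                                     half_life_max = 200) {
  stopifnot(inherits(resistance_counts, "yearly_counts"))
  mode <- match.arg(mode)
  rate_definition <- match.arg(rate_definition)
  dparams <- if (inherits(dfit, "discovery_fit")) dfit$params else dfit
  stopifnot(inherits(dparams, "discovery_params"))
  c_y <- resistance_counts$counts
  if (all(c_y == 0L)) {
    stop("cannot fit: no resistance detections in the counts", call. = FALSE)
  }
  ys <- resistance_counts$start_year + seq_along(c_y) - 1L
  if (mode == "literal_exponential" && is.null(t_onset)) {
    t_onset <- ys[which(c_y > 0L)[1L]]
  }
  lfact <- lfactorial(c_y)
  grid <- c(ys, ys[length(ys)] + 1L)
  ll_h <- function(h) {
    ER <- expected_resistant(grid, dparams, h,
                             mode = mode, t_onset = t_onset,
                             rate_definition = rate_definition)
    nu <- pmax(diff(ER), 0)
    poisson_increment_loglik(c_y, nu, lfact)
  }
  opt <- stats::optimize(ll_h, interval = c(0.05, half_life_max),
                         maximum = TRUE, tol = 1e-8)
  if (!is.finite(opt$objective)) {
    stop("no half-life achieved a finite likelihood", call. = FALSE)
  }
  structure(list(half_life = opt$maximum,
                 hazard = resolve_hazard(opt$maximum, rate_definition),
                 loglik = opt$objective,
                 mode = mode,
                 t_onset = t_onset,
                 rate_definition = rate_definition,
                 counts = resistance_counts,
                 dparams = dparams),
            class = "resistance_detection_fit")
}

#' @export
print.resistance_detection_fit <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Resistance-detection fit (%s, stagewise Poisson ML)\n", x$mode))
  cat(sprintf("  half-life: %s years   hazard: %s /year\n",
              format(x$half_life, digits = digits),
              format(x$hazard, digits = digits)))
  cat(sprintf("  log-likelihood: %s\n", format(x$loglik, digits = digits)))
  invisible(x)
}

#' @export
coef.resistance_detection_fit <- function(object, ...) {
  c(half_life = object$half_life, hazard = object$hazard)
}

#' @export
logLik.resistance_detection_fit <- function(object, ...) {
  structure(object$loglik, df = 1L, nobs = length(object$counts$counts),
            class = "logLik")
}
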