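#' Configuration of the generative timeline simulator
#'
#' Bundles everything the simulator needs to produce a synthetic class
#' timeline table with the statistical structure the analysis assumes:
#' coupon-collector discovery (Poisson draws at rate `n` on one of `k`
#' classes after the lag), exponential per-class time to resistance with
#' median `half_life`, an optional exponential discovery-to-clinical-use
#' delay, and right-censoring at `observation_year`.
#'
#' @param dparams a [discovery_params()].
#' @param half_life median time from discovery to resistance detection,
#'   years `> 0`.
#' @param use_delay_mean mean discovery-to-clinical-use delay in years,
#'   `>= 0` (0 = immediate use); generative garnish only, never fitted.
#' @param horizon_year last calendar year of the discovery process; must
#'   exceed `t0`.
#' @param observation_year censoring horizon, `<= horizon_year`; defaults
#'   to `horizon_year`.
#' @param seed integer seed; every random draw in the simulator flows from
#'   it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(dparams, half_life, use_delay_mean = 8,
                              horizon_year, observation_year = horizon_year,
                              seed) {
  stopifnot(inherits(dparams, "discovery_params"))
  check_scalar(half_life, "half_life", lower = 0, allow_lower = FALSE)
  check_scalar(use_delay_mean, "use_delay_mean", lower = 0)
  check_scalar(horizon_year, "horizon_year")
  check_scalar(observation_year, "observation_year")
  if (horizon_year <= dparams$t0) {
    stop("horizon_year must be after the origin year t0", call. = FALSE)
  }
  if (observation_year > horizon_year) {
    stop("observation_year must not exceed horizon_year", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(dparams = dparams, half_life = half_life,
                 use_delay_mean = use_delay_mean,
                 horizon_year = horizon_year,
                 observation_year = observation_year,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Draw the discovery process under the caller's RNG state (no seeding here;
# the exported wrappers seed exactly once).
draw_discovery <- function(config) {
  p <- config$dparams
  window <- config$horizon_year - p$t0 - p$t_lag
  if (window <= 0) {
    return(list(draws = data.frame(time = numeric(0), class = integer(0)),
                discoveries = data.frame(class = integer(0),
                                         time = numeric(0),
                                         year = integer(0))))
  }
  m <- stats::rpois(1L, p$n * window)
  time <- sort(stats::runif(m, 0, window)) + p$t0 + p$t_lag
  cls <- sample.int(p$k, m, replace = TRUE)
  first <- !duplicated(cls)
  list(draws = data.frame(time = time, class = cls),
       discoveries = data.frame(class = cls[first], time = time[first],
                                year = as.integer(floor(time[first]))))
}

#' Simulate the class-discovery process
#'
#' Draw times form a homogeneous Poisson process at rate `n` per year on
#' `(t0 + t_lag, horizon_year]`; each draw lands uniformly on one of `k`
#' classes; a class's discovery year is the floor of its first draw time.
#' Reproducible given the config seed.
#'
#' @param config a [simulation_config()].
#' @return a list with `draws` (all draw events: `time`, `class`) and
#'   `discoveries` (one row per discovered class: `class`, `time`, `year`).
#' @export
simulate_discovery_process <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, draw_discovery(config))
}

#' Simulate a synthetic class timeline table
#'
#' Runs the discovery process, then gives each discovered class an
#' exponential clinical-use delay (mean `use_delay_mean`; zero means
#' immediate use) and an exponential time to resistance detection with
#' median `half_life`.  Years are floored to integers; a resistance year
#' later than `observation_year` is recorded as missing (right-censored).
#' The returned table satisfies every timeline-table invariant.
#'
#' The continuous (pre-flooring) per-class delays are attached as the
#' `"latent"` attribute -- a data frame with `class_name`,
#' `resistance_delay`, `use_delay` -- for distributional diagnostics of the
#' generator itself.
#'
#' @param config a [simulation_config()].
#' @return a timeline data frame (possibly 0 rows), ordered by discovery.
#' @export
simulate_timelines <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    disc <- draw_discovery(config)$discoveries
    nc <- nrow(disc)
    use_delay <- if (config$use_delay_mean > 0) {
      stats::rexp(nc, rate = 1 / config$use_delay_mean)
    } else {
      numeric(nc)
    }
    res_delay <- stats::rexp(nc, rate = log(2) / config$half_life)
    res_year <- as.integer(floor(disc$year + res_delay))
    res_year[res_year > config$observation_year] <- NA_integer_
    tab <- data.frame(
      class_name = sprintf("class_%03d", disc$class),
      discovery_year = disc$year,
      clinical_use_year = as.integer(floor(disc$year + use_delay)),
      resistance_year = res_year,
      stringsAsFactors = FALSE)
    tab <- tab[order(tab$discovery_year, tab$class_name), , drop = FALSE]
    rownames(tab) <- NULL
    latent <- data.frame(class_name = sprintf("class_%03d", disc$class),
                         resistance_delay = res_delay,
                         use_delay = use_delay,
                         stringsAsFactors = FALSE)
    tab <- validate_timelines(tab)
    attr(tab, "latent") <- latent
    tab
  })
}

#' A small illustrative timeline table
#'
#' A hard-coded 8-row synthetic table loosely echoing the shape of the
#' historical record (a 1930s--1980s discovery span, decades-long spread
#' of resistance delays, one class still without detected resistance).
#' The class names and years are invented for documentation and smoke
#' tests; they are not curated historical ground truth.
#'
#' @return a valid timeline data frame with 8 records, one right-censored.
#' @export
make_fixture <- function() {
  tab <- data.frame(
    class_name = c("synthetic_sulfonamide", "synthetic_beta_lactam",
                   "synthetic_aminoglycoside", "synthetic_tetracycline",
                   "synthetic_macrolide", "synthetic_glycopeptide",
                   "synthetic_quinolone", "synthetic_oxazolidinone"),
    discovery_year = c(1935L, 1940L, 1944L, 1948L, 1952L, 1957L, 1962L, 1987L),
    clinical_use_year = c(1936L, 1943L, 1946L, 1952L, 1955L, 1958L, 1967L,
                          2000L),
    resistance_year = c(1942L, 1947L, 1950L, 1959L, 1968L, 1988L, 1998L,
                        NA_integer_),
    stringsAsFactors = FALSE)
  validate_timelines(tab)
  tab
}
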