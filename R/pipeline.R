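abxdyn_version <- function() {
  as.character(utils::packageVersion("abxdyn"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full discovery-and-resistance pipeline
#'
#' Executes the whole analysis on a timeline table: censored intervals,
#' exponential resistance fit (with optional bootstrap confidence
#' interval), coupon-collector discovery fit, stagewise resistance-
#' detection fit, and the D/R/U dynamics curves.  The input is either a
#' timeline CSV (`input`) or a [simulation_config()] (`sim`), never both.
#'
#' By default the distribution-of-intervals fit uses the uncensored events
#' only (the histogram the distribution panel shows); set
#' `include_censored = TRUE` for the censoring-aware likelihood over all
#' classes.
#'
#' @param input path to a timeline CSV, or a timeline data frame.
#' @param sim a [simulation_config()] to generate the input instead.
#' @param observation_year censoring horizon (default: latest year in the
#'   table, or the simulation's observation year).
#' @param include_censored include right-censored classes in the
#'   interval-distribution fit (default `FALSE`).
#' @param binned use the binned Poisson fit for the interval distribution.
#' @param bin_width bin width for the binned fit, years.
#' @param ci compute a bootstrap confidence interval for the half-life.
#' @param ci_level,n_boot,seed bootstrap settings; `seed` also covers any
#'   other randomness and is recorded in the provenance block.
#' @param k_max,t_lag_max,t0 discovery-fit search bounds and origin.
#' @param mode dynamics mode, `"per_class_hazard"` or
#'   `"literal_exponential"`.
#' @param out_dir if non-`NULL`, write `report.json` and `curves.csv`
#'   there (created if needed); partial outputs are removed on error.
#' @return an object of class `pipeline_report`.
#' @export
run_pipeline <- function(input = NULL, sim = NULL, observation_year = NULL,
                         include_censored = FALSE, binned = FALSE,
                         bin_width = 5, ci = TRUE, ci_level = 0.95,
                         n_boot = 1000, seed = 1, k_max = 200,
                         t_lag_max = 60, t0 = NULL,
                         mode = c("per_class_hazard", "literal_exponential"),
                         out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.null(input) == is.null(sim)) {
    stop("provide exactly one of `input` (CSV/table) or `sim` (config)",
         call. = FALSE)
  }
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "simulation_config"))
    table <- stage("simulate", simulate_timelines(sim))
    observation_year <- observation_year %||% sim$observation_year
    t0 <- t0 %||% sim$dparams$t0
    provenance_input <- list(simulation = list(
      k = sim$dparams$k, n = sim$dparams$n, t_lag = sim$dparams$t_lag,
      t0 = sim$dparams$t0, half_life = sim$half_life,
      use_delay_mean = sim$use_delay_mean, horizon_year = sim$horizon_year,
      observation_year = sim$observation_year, seed = sim$seed))
  } else if (is.character(input)) {
    table <- stage("read", read_timelines(input))
    provenance_input <- list(path = input)
  } else {
    table <- stage("validate", validate_timelines(input))
    provenance_input <- list(path = "<in-memory table>")
  }
  if (nrow(table) < 2L) {
    stop("pipeline needs at least two classes", call. = FALSE)
  }

  intervals <- stage("intervals", compute_intervals(table, observation_year))
  fit_iv <- if (include_censored) intervals else
    intervals[!intervals$censored, , drop = FALSE]
  rfit <- stage("resistance_fit",
                if (binned) fit_exponential_binned_poisson(fit_iv, bin_width)
                else fit_exponential_mle(fit_iv))
  if (ci) {
    rfit$ci_half_life <- stage("resistance_ci",
                               half_life_ci(fit_iv, level = ci_level,
                                            n_boot = n_boot, seed = seed))
  }

  # an explicit origin anchors the counts window, so the fitted lag is
  # measured from it rather than from the first observed discovery
  dcounts <- stage("discovery_counts", discovery_counts(table, start_year = t0))
  dfit <- stage("discovery_fit",
                fit_discovery(dcounts, k_max = k_max, t_lag_max = t_lag_max,
                              t0 = t0))
  rcounts <- stage("resistance_counts",
                   resistance_counts(table, start_year = dcounts$start_year))
  det <- stage("resistance_detection_fit",
               fit_resistance_detection(rcounts, dfit, mode = mode))
  last_year <- max(dcounts$start_year + length(dcounts$counts) - 1L,
                   attr(intervals, "observation_year"))
  years <- dcounts$start_year:last_year
  curves <- stage("curves",
                  undetected_curve(dfit$params, det$half_life, years,
                                   mode = mode, t_onset = det$t_onset))

  report <- structure(list(
    schema_version = "1",
    resistance_fit = list(
      hazard = rfit$hazard, half_life = rfit$half_life,
      ci_half_life = rfit$ci_half_life, n_events = rfit$n_events,
      n_censored = rfit$n_censored, loglik = rfit$loglik,
      method = rfit$method, include_censored = include_censored),
    discovery_fit = list(
      k = dfit$params$k, n = dfit$params$n, t_lag = dfit$params$t_lag,
      t0 = dfit$params$t0, loglik = dfit$loglik,
      converged = dfit$converged),
    detection_fit = list(
      half_life = det$half_life, hazard = det$hazard,
      loglik = det$loglik, mode = det$mode),
    provenance = list(
      input = provenance_input, seed = seed,
      observation_year = attr(intervals, "observation_year"),
      version = abxdyn_version(),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    table = table, intervals = intervals,
    rfit = rfit, dfit = dfit, det = det, curves = curves),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    json_path <- file.path(out_dir, "report.json")
    csv_path <- file.path(out_dir, "curves.csv")
    ok <- FALSE
    on.exit(if (!ok) unlink(c(json_path, csv_path)))
    write_report(report, json_path)
    utils::write.csv(as.data.frame(curves), csv_path, row.names = FALSE,
                     quote = FALSE)
    report$provenance$curves_csv <- csv_path
    ok <- TRUE
  }
  message(sprintf(
    "abxdyn: half_life = %.2f y, k = %d, n = %.3f /y, t_lag = %g y (seed %s)",
    rfit$half_life, dfit$params$k, dfit$params$n, dfit$params$t_lag,
    format(seed)))
  report
}

#' Write a pipeline report as JSON
#'
#' @param report a `pipeline_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  keep <- c("schema_version", "resistance_fit", "discovery_fit",
            "detection_fit", "provenance")
  jsonlite::write_json(report[keep], path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== abxdyn pipeline report (schema", x$schema_version, ") ==\n")
  print(x$rfit)
  print(x$dfit)
  print(x$det)
  print(x$curves)
  invisible(x)
}

#' @export
plot.pipeline_report <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(oldpar))
  tab <- x$table
  iv <- x$intervals
  done <- !iv$censored
  use_delay <- tab$clinical_use_year - tab$discovery_year
  graphics::plot(tab$discovery_year[done], iv$duration[done],
                 pch = 19, col = grDevices::grey(0.3),
                 xlab = "discovery year", ylab = "years to resistance",
                 main = "discovery vs time to resistance",
                 cex = 0.8 + 0.05 * pmin(use_delay[done], 20, na.rm = TRUE))
  ev <- iv$duration[done]
  graphics::hist(ev, breaks = seq(0, max(ev) + 5, by = 5), freq = TRUE,
                 col = "grey85", xlab = "years to resistance",
                 main = "interval distribution")
  tgrid <- seq(0, max(ev) + 5, length.out = 200)
  graphics::lines(tgrid, length(ev) * 5 * x$rfit$hazard *
                    exp(-x$rfit$hazard * tgrid), col = "steelblue", lwd = 2)
  plot(x$curves, main = "discovery / resistance dynamics")
  invisible(x)
}
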