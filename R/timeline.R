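#' Timeline tables of antibacterial drug classes
#'
#' A timeline table records, for each antibacterial drug class, the calendar
#' year of its discovery, of its first clinical use (optional), and of the
#' first detection of clinical resistance (optional).  A missing resistance
#' year means resistance had not been detected by the observation horizon:
#' the class is right-censored.  Tables are plain data frames with columns
#' `class_name`, `discovery_year`, `clinical_use_year`, `resistance_year`;
#' years are integer calendar years and missing values are `NA`.
#'
#' @section Invariants:
#' * `class_name` is unique and non-empty;
#' * `discovery_year` is present for every record;
#' * `clinical_use_year >= discovery_year` when present;
#' * `resistance_year >= discovery_year` when present.
#'
#' @name timeline_table
NULL

TIMELINE_COLUMNS <- c("class_name", "discovery_year",
                      "clinical_use_year", "resistance_year")

#' Validate a timeline table
#'
#' Checks the structural invariants of a class timeline table (see
#' [timeline_table]) and returns the table invisibly, with year columns
#' coerced to integer.  Errors name the offending row.
#'
#' @param table data frame with columns `class_name`, `discovery_year`,
#'   `clinical_use_year`, `resistance_year`.
#' @return the validated table, invisibly.
#' @export
validate_timelines <- function(table) {
  if (!is.data.frame(table)) {
    stop("timeline table must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(TIMELINE_COLUMNS, names(table))
  if (length(missing_cols)) {
    stop("timeline table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  table$class_name <- as.character(table$class_name)
  for (col in TIMELINE_COLUMNS[-1]) {
    x <- table[[col]]
    if (is.character(x)) x <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & (!is.finite(x) | x != trunc(x))
    if (any(bad)) {
      stop(sprintf("row %d: %s = %s is not an integer calendar year",
                   which(bad)[1L], col, format(x[which(bad)[1L]])),
           call. = FALSE)
    }
    table[[col]] <- as.integer(x)
  }
  if (nrow(table) == 0L) return(invisible(table))

  if (any(is.na(table$class_name) | !nzchar(table$class_name))) {
    stop(sprintf("row %d: class_name is empty",
                 which(is.na(table$class_name) | !nzchar(table$class_name))[1L]),
         call. = FALSE)
  }
  if (anyDuplicated(table$class_name)) {
    dup <- table$class_name[duplicated(table$class_name)][1L]
    stop(sprintf("duplicate class_name '%s' (row %d)", dup,
                 which(table$class_name == dup)[2L]), call. = FALSE)
  }
  if (anyNA(table$discovery_year)) {
    stop(sprintf("row %d: discovery_year is missing",
                 which(is.na(table$discovery_year))[1L]), call. = FALSE)
  }
  bad_use <- !is.na(table$clinical_use_year) &
    table$clinical_use_year < table$discovery_year
  if (any(bad_use)) {
    stop(sprintf("row %d ('%s'): clinical_use_year %d precedes discovery_year %d",
                 which(bad_use)[1L], table$class_name[which(bad_use)[1L]],
                 table$clinical_use_year[which(bad_use)[1L]],
                 table$discovery_year[which(bad_use)[1L]]), call. = FALSE)
  }
  bad_res <- !is.na(table$resistance_year) &
    table$resistance_year < table$discovery_year
  if (any(bad_res)) {
    stop(sprintf("row %d ('%s'): resistance_year %d precedes discovery_year %d",
                 which(bad_res)[1L], table$class_name[which(bad_res)[1L]],
                 table$resistance_year[which(bad_res)[1L]],
                 table$discovery_year[which(bad_res)[1L]]), call. = FALSE)
  }
  invisible(table)
}

#' Read a class timeline table from CSV
#'
#' Reads the canonical comma-separated dialect: UTF-8, header row required
#' with the four columns of [timeline_table], empty cells meaning missing.
#' Row order is preserved and all invariants are checked on load;
#' non-integer years are rejected.
#'
#' @param path path to a CSV file.
#' @return a validated timeline data frame.
#' @seealso [write_timelines()], [compute_intervals()]
#' @export
read_timelines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL,
                         fileEncoding = "UTF-8")
  if (anyDuplicated(names(raw))) {
    stop("malformed header: duplicate column '",
         names(raw)[duplicated(names(raw))][1L], "'", call. = FALSE)
  }
  missing_cols <- setdiff(TIMELINE_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("malformed header: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[TIMELINE_COLUMNS]
  for (col in TIMELINE_COLUMNS[-1]) {
    x <- trimws(raw[[col]])
    x[x == ""] <- NA_character_
    bad <- !is.na(x) & !grepl("^-?[0-9]+$", x)
    if (any(bad)) {
      stop(sprintf("row %d: %s = '%s' is not an integer calendar year",
                   which(bad)[1L], col, x[which(bad)[1L]]), call. = FALSE)
    }
    raw[[col]] <- as.integer(x)
  }
  tab <- validate_timelines(raw)
  rownames(tab) <- NULL
  tab
}

#' Write a class timeline table to CSV
#'
#' Writes the canonical dialect read by [read_timelines()]: comma separator,
#' header row, empty cells for missing years (never sentinel numbers), no
#' quoting.  Reading a written file reproduces the table exactly, and
#' write-read-write is byte stable.
#'
#' @param table a valid timeline data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timelines <- function(table, path) {
  table <- validate_timelines(table)
  if (any(grepl('[",\n\r]', table$class_name))) {
    stop("class_name values must not contain commas, quotes or newlines ",
         "in the canonical CSV dialect", call. = FALSE)
  }
  utils::write.table(table[TIMELINE_COLUMNS], file = path, sep = ",",
                     row.names = FALSE, col.names = TRUE, quote = FALSE,
                     na = "", fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Construct an interval set directly
#'
#' An interval set holds discovery-to-resistance durations with
#' right-censoring flags, the input to the resistance-side fits.  Censored
#' entries contribute exposure time (observation horizon minus discovery)
#' but no event.
#'
#' @param duration numeric vector of durations in years, all `>= 0`.
#' @param censored logical vector; `TRUE` = resistance not yet detected.
#' @param class_name optional labels (default `interval_1`, ...).
#' @param observation_year the censoring horizon, attached as an attribute.
#' @return a data frame of class `interval_set` with columns `class_name`,
#'   `duration`, `censored`.
#' @export
interval_set <- function(duration, censored = rep(FALSE, length(duration)),
                         class_name = paste0("interval_", seq_along(duration)),
                         observation_year = NA_integer_) {
  if (length(duration) != length(censored)) {
    stop("duration and censored must have equal length", call. = FALSE)
  }
  if (any(!is.finite(duration) | duration < 0)) {
    stop("all durations must be finite and >= 0", call. = FALSE)
  }
  out <- data.frame(class_name = as.character(class_name),
                    duration = as.numeric(duration),
                    censored = as.logical(censored),
                    stringsAsFactors = FALSE)
  attr(out, "observation_year") <- observation_year
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Compute censored discovery-to-resistance intervals
#'
#' For every class discovered by `observation_year`, computes the time from
#' discovery to resistance detection.  Classes with a recorded resistance
#' year yield an uncensored duration `resistance_year - discovery_year`
#' (zero-duration events are kept); classes without one are right-censored
#' at `observation_year - discovery_year`.
#'
#' @param table a valid timeline data frame.
#' @param observation_year censoring horizon; defaults to the maximum year
#'   appearing anywhere in the table.  Must be at least the latest
#'   discovery year.
#' @return an [interval_set()] with one entry per record.
#' @export
compute_intervals <- function(table, observation_year = NULL) {
  table <- validate_timelines(table)
  if (nrow(table) == 0L) {
    return(interval_set(numeric(0), logical(0), character(0),
                        observation_year %||% NA_integer_))
  }
  if (is.null(observation_year)) {
    observation_year <- max(c(table$discovery_year, table$clinical_use_year,
                              table$resistance_year), na.rm = TRUE)
  }
  check_scalar(observation_year, "observation_year", integer = TRUE)
  if (observation_year < max(table$discovery_year)) {
    stop(sprintf(
      "observation_year %d precedes the discovery year %d of '%s': cannot censor before discovery",
      observation_year, max(table$discovery_year),
      table$class_name[which.max(table$discovery_year)]), call. = FALSE)
  }
  censored <- is.na(table$resistance_year)
  duration <- ifelse(censored,
                     observation_year - table$discovery_year,
                     table$resistance_year - table$discovery_year)
  interval_set(duration, censored, table$class_name, observation_year)
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("Interval set: %d classes (%d events, %d censored)",
              nrow(x), sum(!x$censored), sum(x$censored)))
  oy <- attr(x, "observation_year")
  if (!is.null(oy) && !is.na(oy)) cat(sprintf(", observation year %d", oy))
  cat("\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Yearly new-class counts
#'
#' A run of consecutive calendar years with the number of classes whose
#' discovery (or first resistance detection) fell in each year.  The
#' cumulative sum of discovery counts is the observed discovery curve D.
#'
#' @param counts non-negative integer vector, one entry per year.
#' @param start_year calendar year of the first entry.
#' @return an object of class `yearly_counts`.
#' @export
yearly_counts <- function(counts, start_year) {
  check_scalar(start_year, "start_year", integer = TRUE)
  if (any(!is.finite(counts) | counts < 0 | counts != trunc(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(list(start_year = as.integer(start_year),
                 counts = as.integer(counts)),
            class = "yearly_counts")
}

#' @export
print.yearly_counts <- function(x, ...) {
  cat(sprintf("Yearly counts: %d years from %d, %d events total\n",
              length(x$counts), x$start_year, sum(x$counts)))
  invisible(x)
}

# Tabulate a vector of calendar years into a yearly_counts covering
# [start_year, end_year].
tabulate_years <- function(years, start_year, end_year) {
  years <- years[!is.na(years)]
  span <- start_year:end_year
  counts <- vapply(span, function(y) sum(years == y), integer(1))
  yearly_counts(counts, start_year)
}

#' Yearly counts of newly discovered classes
#'
#' @param table a valid timeline data frame.
#' @param start_year,end_year window bounds; default to the span of the
#'   discovery years (end extended to the latest year in the table so the
#'   window matches the resistance series).
#' @return a [yearly_counts()] of first discoveries per year.
#' @export
discovery_counts <- function(table, start_year = NULL, end_year = NULL) {
  table <- validate_timelines(table)
  if (nrow(table) == 0L) stop("empty timeline table", call. = FALSE)
  start_year <- start_year %||% min(table$discovery_year)
  end_year <- end_year %||% max(c(table$discovery_year, table$clinical_use_year,
                                  table$resistance_year), na.rm = TRUE)
  tabulate_years(table$discovery_year, start_year, end_year)
}

#' Yearly counts of first resistance detections
#'
#' @inheritParams discovery_counts
#' @return a [yearly_counts()] of first resistance detections per year;
#'   censored classes contribute nothing.
#' @export
resistance_counts <- function(table, start_year = NULL, end_year = NULL) {
  table <- validate_timelines(table)
  if (nrow(table) == 0L) stop("empty timeline table", call. = FALSE)
  start_year <- start_year %||% min(table$discovery_year)
  end_year <- end_year %||% max(c(table$discovery_year, table$clinical_use_year,
                                  table$resistance_year), na.rm = TRUE)
  tabulate_years(table$resistance_year, start_year, end_year)
}
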