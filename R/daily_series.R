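#' Daily outcome and environment time series
#'
#' A `daily_series` is a validated `data.frame` with one row per calendar
#' day, holding emergency-visit counts (total and subgroups) together with
#' meteorological and air-pollution covariates. It is the common input of
#' every model-fitting and simulation function in the package.
#'
#' Recognised columns (all optional except `date`):
#' \describe{
#'   \item{`date`}{calendar date (`Date`), consecutive days, no gaps}
#'   \item{`t`}{0-based integer day index; derived from `date` if absent}
#'   \item{counts}{`stroke`, `is`, `hs`, `age_lt65`, `age_ge65`, `male`,
#'     `female` — non-negative integers}
#'   \item{weather}{`temp_mean` (deg C), `tv` (diurnal range, deg C, >= 0),
#'     `rh` (\%, in \[0, 100\]), `pressure` (hPa), `precip` (mm),
#'     `wind` (m/s)}
#'   \item{pollution}{`no2`, `so2`, `o3`, `pm25`, `pm10` (ug/m3),
#'     `co` (mg/m3)}
#' }
#'
#' Subgroup counts are expected to add up to the total (`is + hs = stroke`,
#' the two age groups and the two sexes likewise); mismatches are reported
#' with a warning rather than an error because real extracts may contain
#' unclassifiable cases.
#'
#' @param data a `data.frame` with at least a `date` column (`Date` or
#'   ISO-8601 character).
#' @return `data` with class `c("daily_series", "data.frame")`, a `t` index
#'   column, and an attribute `missing_covariates` naming recognised
#'   covariates absent from the table.
#' @seealso [read_daily_series()], [summarize_daily_series()],
#'   [simulate_stroke_series()]
#' @export
daily_series <- function(data) {
  stopifnot(is.data.frame(data))
  if (!"date" %in% names(data))
    stop("'data' must contain a 'date' column")
  data$date <- as.Date(data$date)
  if (anyNA(data$date)) stop("unparseable dates in 'date' column")
  n <- nrow(data)
  if (n < 1L) stop("empty series")

  d <- diff(as.integer(data$date))
  if (any(d <= 0L))
    stop("dates must be strictly increasing (first violation after ",
         format(data$date[which(d <= 0L)[1L]]), ")")
  if (any(d > 1L))
    stop("gap after ", format(data$date[which(d > 1L)[1L]]))

  data$t <- seq_len(n) - 1L

  for (cn in intersect(count_columns(), names(data))) {
    v <- data[[cn]]
    bad <- which(!is.na(v) & (v < 0 | v != round(v)))
    if (length(bad))
      stop("column '", cn, "': negative or non-integer count at row ",
           bad[1L])
    data[[cn]] <- as.integer(round(v))
  }
  check_subgroup_sums(data)

  if ("rh" %in% names(data) &&
      any(data$rh < 0 | data$rh > 100, na.rm = TRUE))
    stop("'rh' must lie in [0, 100]")
  if ("tv" %in% names(data) && any(data$tv < 0, na.rm = TRUE))
    stop("'tv' must be non-negative")

  attr(data, "missing_covariates") <-
    setdiff(covariate_columns(), names(data))
  class(data) <- c("daily_series", "data.frame")
  data
}

count_columns <- function() {
  c("stroke", "is", "hs", "age_lt65", "age_ge65", "male", "female")
}

covariate_columns <- function() {
  c("temp_mean", "tv", "rh", "pressure", "precip", "wind",
    "no2", "so2", "o3", "pm25", "pm10", "co")
}

check_subgroup_sums <- function(data) {
  splits <- list(c("is", "hs"), c("age_lt65", "age_ge65"),
                 c("male", "female"))
  for (parts in splits) {
    if (!all(c("stroke", parts) %in% names(data))) next
    tot <- data[[parts[1L]]] + data[[parts[2L]]]
    bad <- which(!is.na(tot) & !is.na(data$stroke) & tot != data$stroke)
    if (length(bad))
      warning(paste(parts, collapse = " + "), " != stroke on ",
              length(bad), " day(s): ",
              paste(format(data$date[head(bad, 5L)]), collapse = ", "),
              if (length(bad) > 5L) ", ..." else "")
  }
  invisible(NULL)
}

#' Read a daily series from CSV
#'
#' Reads the canonical comma-separated dialect (UTF-8, ISO-8601 dates, "."
#' decimal separator, empty cell = missing) and validates the result via
#' [daily_series()].
#'
#' @param path path to a CSV file with a header row.
#' @param column_map optional named character vector mapping file column
#'   names to canonical names, e.g. `c(meantemp = "temp_mean")`.
#' @return a [daily_series()].
#' @export
read_daily_series <- function(path, column_map = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (!is.null(column_map)) {
    hit <- match(names(df), names(column_map))
    names(df)[!is.na(hit)] <- unname(column_map[hit[!is.na(hit)]])
  }
  daily_series(df)
}

#' Write a daily series to CSV
#'
#' Writes the canonical CSV dialect used by [read_daily_series()]; a
#' read/write cycle round-trips the file byte-identically.
#'
#' @param x a [daily_series()] (or plain data.frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_daily_series <- function(x, path) {
  out <- as.data.frame(x)
  out$date <- format(out$date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Descriptive summary of a daily series
#'
#' One row per count and covariate column with mean, SD, minimum, quartiles
#' and maximum, in the first-table layout customary in time-series studies.
#' Quantiles use the same linear-interpolation rule as
#' [quantile_cutpoints()]. Columns that are entirely missing yield a row of
#' `NA`s rather than an error.
#'
#' @param series a [daily_series()].
#' @return a `data.frame` with columns `variable`, `mean`, `sd`, `min`,
#'   `p25`, `median`, `p75`, `max`, `n_missing`.
#' @export
summarize_daily_series <- function(series) {
  stopifnot(nrow(series) >= 2L)
  vars <- intersect(c(count_columns(), covariate_columns()), names(series))
  rows <- lapply(vars, function(v) {
    x <- series[[v]]
    nm <- sum(is.na(x))
    x <- x[!is.na(x)]
    if (!length(x))
      return(data.frame(variable = v, mean = NA_real_, sd = NA_real_,
                        min = NA_real_, p25 = NA_real_, median = NA_real_,
                        p75 = NA_real_, max = NA_real_, n_missing = nm))
    q <- quantile_cutpoints(x, c(0.25, 0.5, 0.75))
    data.frame(variable = v, mean = mean(x), sd = sd(x), min = min(x),
               p25 = q[1L], median = q[2L], p75 = q[3L], max = max(x),
               n_missing = nm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
summary.daily_series <- function(object, ...) summarize_daily_series(object)

#' @export
print.daily_series <- function(x, ...) {
  cat("Daily series: ", nrow(x), " days (",
      format(x$date[1L]), " to ", format(x$date[nrow(x)]), ")\n", sep = "")
  cnts <- intersect(count_columns(), names(x))
  covs <- intersect(covariate_columns(), names(x))
  cat("  counts:     ", paste(cnts, collapse = ", "), "\n", sep = "")
  cat("  covariates: ", paste(covs, collapse = ", "), "\n", sep = "")
  miss <- attr(x, "missing_covariates")
  if (length(miss))
    cat("  absent:     ", paste(miss, collapse = ", "), "\n", sep = "")
  invisible(x)
}
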