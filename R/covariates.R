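#' Mean winter temperature for one winter
#'
#' A winter is labeled by the calendar year of its December and spans
#' December 1 of that year through February 28 of the next; February 29 is
#' excluded in leap years so every winter averages the same 90-day window.
#'
#' Daily series need complete coverage of the window (any missing or NA day
#' is an error). Monthly series are averaged weighting December, January and
#' February by their lengths (31/31/28).
#'
#' @param climate A data frame: either daily with columns `date` (Date or
#'   ISO-8601 string) and `temp_c`, or monthly with columns `year`, `month`
#'   and `temp_c`.
#' @param winter_year Calendar year of the winter's December.
#' @return Mean temperature over the window, in degrees C.
#' @examples
#' monthly <- data.frame(year = c(2000, 2001, 2001),
#'                       month = c(12, 1, 2), temp_c = c(-2, -6, -4))
#' winter_mean(monthly, 2000)  # (31*-2 + 31*-6 + 28*-4) / 90
#' @export
winter_mean <- function(climate, winter_year) {
  stopifnot(is.numeric(winter_year), length(winter_year) == 1)
  climate <- tibble::as_tibble(climate)
  if (all(c("date", "temp_c") %in% names(climate))) {
    winter_mean_daily(climate, winter_year)
  } else if (all(c("year", "month", "temp_c") %in% names(climate))) {
    winter_mean_monthly(climate, winter_year)
  } else {
    stop("climate must have columns date/temp_c (daily) or year/month/temp_c (monthly)",
         call. = FALSE)
  }
}

winter_window_days <- function(winter_year) {
  dec <- seq(as.Date(sprintf("%d-12-01", winter_year)),
             as.Date(sprintf("%d-12-31", winter_year)), by = "day")
  janfeb <- seq(as.Date(sprintf("%d-01-01", winter_year + 1)),
                as.Date(sprintf("%d-02-28", winter_year + 1)), by = "day")
  c(dec, janfeb)  # 90 days; Feb 29 never included
}

winter_mean_daily <- function(climate, winter_year) {
  dates <- as.Date(climate$date)
  window <- winter_window_days(winter_year)
  idx <- match(window, dates)
  temps <- climate$temp_c[idx]
  if (anyNA(idx) || anyNA(temps)) {
    n_missing <- sum(is.na(idx) | is.na(temps))
    stop("winter ", winter_year, ": ", n_missing,
         " missing day(s) in the Dec 1-Feb 28 window", call. = FALSE)
  }
  mean(temps)
}

winter_mean_monthly <- function(climate, winter_year) {
  pick <- function(yr, mo) {
    v <- climate$temp_c[climate$year == yr & climate$month == mo]
    if (length(v) != 1 || is.na(v)) {
      stop("winter ", winter_year, ": missing monthly temperature for ",
           yr, "-", sprintf("%02d", mo), call. = FALSE)
    }
    v
  }
  w <- c(31, 31, 28)
  temps <- c(pick(winter_year, 12), pick(winter_year + 1, 1), pick(winter_year + 1, 2))
  sum(w * temps) / sum(w)
}

#' Winter temperature anomaly relative to a fixed baseline
#'
#' The anomaly is the winter mean minus the mean of winter means over the
#' baseline winters (default winters labeled 1981 through 2010), so winters
#' colder than the long-term average get negative values.
#'
#' @inheritParams winter_mean
#' @param baseline Length-2 integer vector: first and last winter label of
#'   the baseline period.
#' @return Anomaly in degrees C.
#' @export
winter_anomaly <- function(climate, winter_year, baseline = c(1981, 2010)) {
  winter_mean(climate, winter_year) - baseline_mean(climate, baseline)
}

baseline_mean <- function(climate, baseline) {
  stopifnot(length(baseline) == 2, baseline[1] <= baseline[2])
  mean(vapply(seq(baseline[1], baseline[2]), function(y) winter_mean(climate, y),
              numeric(1)))
}

#' Winter covariate table for a span of winters
#'
#' @inheritParams winter_anomaly
#' @param winter_years Integer vector of winter labels to compute.
#' @return A tibble with columns `winter_year`, `mean_temp_c`, `anomaly_c`.
#' @export
winter_covariates <- function(climate, winter_years, baseline = c(1981, 2010)) {
  base <- baseline_mean(climate, baseline)
  means <- vapply(winter_years, function(y) winter_mean(climate, y), numeric(1))
  tibble::tibble(winter_year = as.integer(winter_years),
                 mean_temp_c = means,
                 anomaly_c = means - base)
}

#' Prey abundance index per 100 trap nights
#'
#' @param captures Non-negative capture counts.
#' @param trap_nights Positive trap-night counts (one trap set for one night).
#' @return `100 * captures / trap_nights`, vectorized.
#' @examples
#' prey_index(48, 384)  # 12.5 captures per 100 trap nights
#' @export
prey_index <- function(captures, trap_nights) {
  if (any(!is.finite(trap_nights)) || any(trap_nights <= 0)) {
    stop("trap_nights must be positive", call. = FALSE)
  }
  if (any(!is.finite(captures)) || any(captures < 0)) {
    stop("captures must be non-negative", call. = FALSE)
  }
  100 * captures / trap_nights
}

#' Standardize a numeric vector to zero mean and unit SD
#'
#' Z-scoring is applied over the analysis sample actually entering a model,
#' so each analysis set is standardized separately.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return `(x - mean(x)) / sd(x)`.
#' @export
standardize <- function(x) {
  if (!is.numeric(x) || sum(is.finite(x)) < 2) {
    stop("standardize() needs at least two finite values", call. = FALSE)
  }
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize a constant vector", call. = FALSE)
  }
  (x - mean(x, na.rm = TRUE)) / s
}
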