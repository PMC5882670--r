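#' Growing degree-days over a window
#'
#' Accumulates mean daily temperature above a base threshold over a calendar
#' window: `gdd = sum(max(T_d - base_temp, 0))` over the days of the window
#' present in the series. Days absent from the series are counted as missing
#' and excluded, never imputed.
#'
#' The base temperature is configurable and defaults to 0 degrees C; growth
#' thresholds for cold-water salmonids are debated and any fixed choice should
#' be stated alongside the resulting degree-day sums.
#'
#' @param series Data frame with columns `date` (coercible to `Date`) and
#'   `value` (mean daily temperature, degrees C).
#' @param window Length-2 vector of dates, the inclusive window
#'   `c(start, end)`.
#' @param base_temp Base temperature in degrees C (default 0).
#' @param label Optional label for the window (e.g. a year).
#' @return A one-row tibble: `label`, `gdd`, `base_temp`, `n_days_used`,
#'   `n_days_missing`.
#' @examples
#' s <- tibble::tibble(date = as.Date("2010-01-01") + 0:9, value = 10)
#' compute_gdd(s, c(as.Date("2010-01-01"), as.Date("2010-01-10")))
#' @export
compute_gdd <- function(series, window, base_temp = 0, label = NULL) {
  assert_columns(series, c("date", "value"), "`series`")
  window <- as.Date(window)
  if (length(window) != 2 || is.na(window[1]) || is.na(window[2]) ||
      window[1] > window[2]) {
    abort("`window` must be two dates c(start, end) with start <= end.")
  }
  days <- seq(window[1], window[2], by = "day")
  sub <- series |>
    dplyr::mutate(date = as.Date(.data$date)) |>
    dplyr::filter(.data$date >= window[1], .data$date <= window[2]) |>
    dplyr::distinct(.data$date, .keep_all = TRUE)
  if (nrow(sub) == 0) {
    abort(sprintf("temperature series has no days in window %s..%s",
                  format(window[1]), format(window[2])))
  }
  tibble::tibble(
    label = label %||% paste0(format(window[1]), "..", format(window[2])),
    gdd = sum(pmax(sub$value - base_temp, 0)),
    base_temp = base_temp,
    n_days_used = nrow(sub),
    n_days_missing = length(days) - nrow(sub)
  )
}

#' Mean temperature over a sampling interval
#'
#' Arithmetic mean of daily values over `[start, end)` — the covariate used
#' for survival between two sampling occasions. Input rows may arrive in any
#' order; dates are sorted and de-duplicated internally.
#'
#' @inheritParams compute_gdd
#' @param start,end Interval bounds (start inclusive, end exclusive).
#' @return One-row tibble: `mean_temp`, `n_days_used`, `frac_missing`.
#' @export
mean_interval_temperature <- function(series, start, end) {
  assert_columns(series, c("date", "value"), "`series`")
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || start >= end) {
    abort("`start` must precede `end`.")
  }
  sub <- series |>
    dplyr::mutate(date = as.Date(.data$date)) |>
    dplyr::filter(.data$date >= start, .data$date < end) |>
    dplyr::distinct(.data$date, .keep_all = TRUE) |>
    dplyr::arrange(.data$date)
  n_window <- as.integer(end - start)
  if (nrow(sub) == 0) {
    abort(sprintf("temperature series has no days in interval %s..%s",
                  format(start), format(end)))
  }
  tibble::tibble(
    mean_temp = mean(sub$value),
    n_days_used = nrow(sub),
    frac_missing = 1 - nrow(sub) / n_window
  )
}

#' Percentile rank within a sample of annual maxima
#'
#' Empirical percentile rank of `value` within a sample of annual maxima
#' (e.g. daily-rainfall annual maxima), used to place an observed event within
#' the historical record. The convention is counting / nearest-rank:
#' `100 * mean(maxima <= value)`, so the sample maximum sits at the 100th
#' percentile and any value below the sample minimum at the 0th.
#'
#' @param annual_maxima Numeric vector of annual maxima (at least 2).
#' @param value The value to rank (same units).
#' @return Percentile rank in `[0, 100]`.
#' @examples
#' maxima_percentile(1:100, 95)
#' @export
maxima_percentile <- function(annual_maxima, value) {
  annual_maxima <- annual_maxima[!is.na(annual_maxima)]
  if (length(annual_maxima) < 2) {
    abort("need at least 2 annual maxima to compute a percentile rank.")
  }
  100 * mean(annual_maxima <= value)
}
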