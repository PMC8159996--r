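#' Default 8-day composite calendar for the growing season
#'
#' Satellite composites aggregate observations over standard 8-day windows
#' whose start days-of-year are 1, 9, 17, ... Restricting to the growing
#' season (March-October) keeps the windows starting on days 65 through 297,
#' which is exactly `T = 30` composites per year.
#'
#' @param T_steps Number of composites per season (default 30).
#' @param first_start_doy Start day-of-year of the first retained composite
#'   (default 65, the 9th standard 8-day window).
#' @param step Days between composite starts (default 8).
#' @return Named integer vector mapping time index `1..T` to the composite
#'   start day-of-year.
#' @export
composite_calendar <- function(T_steps = 30L, first_start_doy = 65L, step = 8L) {
  stopifnot(T_steps >= 1L, first_start_doy >= 1L, step >= 1L)
  doy <- first_start_doy + step * (seq_len(T_steps) - 1L)
  if (any(doy > 366L)) {
    stop("composite calendar extends past day-of-year 366")
  }
  stats::setNames(as.integer(doy), seq_len(T_steps))
}

#' Convert a month/day forecast date to a day-of-year
#'
#' Uses a non-leap civil calendar, matching the fixed composite calendar.
#'
#' @param month Month number 1-12.
#' @param day Day of month.
#' @return Integer day-of-year.
#' @export
forecast_doy <- function(month, day) {
  days_in_month <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  stopifnot(length(month) == 1L, length(day) == 1L)
  month <- as.integer(month)
  day <- as.integer(day)
  if (is.na(month) || month < 1L || month > 12L) stop("month must be in 1..12")
  if (is.na(day) || day < 1L || day > days_in_month[month]) {
    stop("day ", day, " invalid for month ", month)
  }
  as.integer(sum(days_in_month[seq_len(month - 1L)]) + day)
}

#' The four in-season forecast dates used by the evaluation protocol
#'
#' The 23rd of July, August, September and October, expressed as
#' days-of-year (204, 235, 266, 296 on the non-leap calendar).
#'
#' @return Named integer vector of days-of-year.
#' @export
default_forecast_dates <- function() {
  c(jul = forecast_doy(7L, 23L), aug = forecast_doy(8L, 23L),
    sep = forecast_doy(9L, 23L), oct = forecast_doy(10L, 23L))
}
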