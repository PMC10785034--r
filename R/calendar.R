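# Simulation calendar: a 365-day non-leap year in local standard time, so
# daily-maximum windows are well defined without DST or leap complications.
# The year may start at any calendar month (an April start matches an
# April-to-March assessment window).

MONTH_LENGTHS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Calendar month of each simulation day
#'
#' Simulation days count from 1 at the first day of `start_month` of a
#' 365-day non-leap year; the sequence wraps across year boundaries, so day
#' 366 has the same month as day 1.
#'
#' @param day Integer day-of-simulation (1-based), vectorised.
#' @param start_month Calendar month (1-12) of simulation day 1.
#' @return Integer calendar months in 1..12.
#' @export
month_of_day <- function(day, start_month = 4L) {
  if (any(day < 1)) stop("day must be >= 1")
  order <- ((start_month - 1L + 0:11) %% 12L) + 1L
  month_per_doy <- rep(order, MONTH_LENGTHS[order])
  month_per_doy[((day - 1L) %% 365L) + 1L]
}

#' Day-of-calendar-year of each simulation day
#'
#' Position (1..365) of a simulation day within the standard calendar year,
#' used to evaluate seasonal cycles. With `start_month = 4`, simulation day 1
#' is calendar day 91 (April 1).
#'
#' @inheritParams month_of_day
#' @export
doy_of_day <- function(day, start_month = 4L) {
  offset <- if (start_month == 1L) 0L else sum(MONTH_LENGTHS[seq_len(start_month - 1L)])
  ((offset + (day - 1L)) %% 365L) + 1L
}
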