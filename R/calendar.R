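#' Study calendar for a single-year CDR analysis
#'
#' Defines the time axis shared by every trajectory matrix: days of the study
#' year and the mapping from days to coarser bins. Four resolutions are
#' supported: `daily` (365 bins for a non-leap year, 366 for a leap year),
#' `weekly` (consecutive 7-day blocks anchored at Jan 1; the final bin holds
#' the 1-2 leftover days, giving 53 bins), `biweekly` (two half-month bins per
#' calendar month, days 1-15 and 16-end, giving 24 bins) and `monthly`
#' (12 calendar months).
#'
#' Event timestamps are carried internally as integer 10-minute tick indices
#' from midnight of Jan 1 (tick 0), with 144 ticks per day. A single timezone
#' is assumed throughout.
#'
#' @param year Study year (default 2013).
#' @return A `study_calendar` object: list with `year`, `n_days`, `start`
#'   (POSIXct, UTC), and per-resolution bin assignments for each day.
#' @examples
#' cal <- study_calendar(2013)
#' n_bins(cal, "monthly")  # 12
#' @export
study_calendar <- function(year = 2013L) {
  year <- as.integer(year)
  start <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC")
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  n_days <- length(dates)
  month <- as.integer(format(dates, "%m"))
  dom <- as.integer(format(dates, "%d"))
  day_bin <- list(
    daily    = seq_len(n_days),
    weekly   = pmin((seq_len(n_days) - 1L) %/% 7L + 1L, 53L),
    biweekly = 2L * month - as.integer(dom <= 15L),
    monthly  = month
  )
  structure(
    list(year = year, n_days = n_days, start = start, day_bin = day_bin),
    class = "study_calendar"
  )
}

#' @export
print.study_calendar <- function(x, ...) {
  cat(sprintf("study_calendar: year %d, %d days; bins: %s\n",
              x$year, x$n_days,
              paste(sprintf("%s=%d", names(x$day_bin),
                            vapply(x$day_bin, max, integer(1))),
                    collapse = ", ")))
  invisible(x)
}

#' Number of time bins at a resolution
#' @param calendar A [study_calendar()].
#' @param resolution One of `"daily"`, `"weekly"`, `"biweekly"`, `"monthly"`.
#' @return Integer bin count (365/53/24/12 for a 365-day year).
#' @export
n_bins <- function(calendar, resolution) {
  stopifnot(inherits(calendar, "study_calendar"))
  resolution <- match.arg(resolution, names(calendar$day_bin))
  max(calendar$day_bin[[resolution]])
}

#' Map each day of the study year to its bin at a resolution
#' @inheritParams n_bins
#' @return Integer vector of length `calendar$n_days`.
#' @export
day_bins <- function(calendar, resolution) {
  stopifnot(inherits(calendar, "study_calendar"))
  resolution <- match.arg(resolution, names(calendar$day_bin))
  calendar$day_bin[[resolution]]
}

# 10-minute ticks per day
TICKS_PER_DAY <- 144L

#' Convert ISO-8601 timestamps to 10-minute tick indices
#'
#' Tick 0 is 00:00-00:10 of Jan 1 of the study year. Unparseable timestamps
#' map to NA.
#' @param ts Character vector of ISO-8601 timestamps (`YYYY-MM-DDTHH:MM:SS`,
#'   a space separator is also accepted).
#' @param calendar A [study_calendar()].
#' @return Integer tick indices (NA where unparseable or out of range handled
#'   by the caller).
#' @export
timestamp_to_tick <- function(ts, calendar) {
  ts <- gsub("T", " ", as.character(ts), fixed = TRUE)
  t <- as.POSIXct(strptime(ts, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  miss <- is.na(t)
  if (any(miss))  # date-only fallback; anything else stays NA (rejected)
    t[miss] <- as.POSIXct(strptime(ts[miss], "%Y-%m-%d", tz = "UTC"))
  as.integer(floor(as.numeric(difftime(t, calendar$start, units = "secs")) / 600))
}

#' Convert tick indices back to ISO-8601 timestamps
#' @param tick Integer tick indices.
#' @inheritParams timestamp_to_tick
#' @return Character ISO-8601 timestamps at the tick start.
#' @export
tick_to_timestamp <- function(tick, calendar) {
  format(calendar$start + as.numeric(tick) * 600, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' Day of the study year for each tick (1-based)
#' @inheritParams tick_to_timestamp
#' @return Integer day-of-year.
#' @export
tick_to_day <- function(tick, calendar) {
  as.integer(tick %/% TICKS_PER_DAY + 1L)
}
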