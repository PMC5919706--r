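#' Read anonymized call events
#'
#' Reads a delimited file of call events with header
#' `user_id,timestamp,region_id` (the layout used for year-long,
#' region-quantized operator exports). Timestamps are ISO-8601 and are
#' quantized internally to 10-minute ticks from the study start. Records with
#' an unknown region or an unparseable/out-of-period timestamp are rejected
#' with a warning (or raise an error in strict mode).
#'
#' @param path Delimited text file (comma or tab separated, with header).
#' @param partition A [region_partition()] declaring the valid regions.
#' @param calendar A [study_calendar()] declaring the study period.
#' @param strict If `TRUE`, any invalid record is an error instead of a
#'   rejection.
#' @return An `event_table`: data.table with columns `user_id` (character),
#'   `tick` (integer), `day` (integer day-of-year), `region_id` (character),
#'   sorted by (user_id, tick); attribute `rejected` holds the rejected
#'   record count.
#' @export
read_events <- function(path, partition, calendar, strict = FALSE) {
  stopifnot(inherits(partition, "region_partition"),
            inherits(calendar, "study_calendar"))
  dt <- data.table::fread(path, showProgress = FALSE,
                          colClasses = list(
                            character = c("user_id", "timestamp",
                                          "region_id")))
  if (nrow(dt) == 0L) {
    warning("empty event file: ", path)
    return(event_table(data.table::data.table(
      user_id = character(), tick = integer(), day = integer(),
      region_id = character()), rejected = 0L))
  }
  need <- c("user_id", "timestamp", "region_id")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("event file missing columns: ",
                         paste(miss, collapse = ", "))
  dt[, `:=`(user_id = as.character(user_id),
            region_id = as.character(region_id))]
  tick <- suppressWarnings(timestamp_to_tick(dt$timestamp, calendar))
  max_tick <- calendar$n_days * TICKS_PER_DAY - 1L
  bad_time <- is.na(tick) | tick < 0L | tick > max_tick
  bad_region <- !(dt$region_id %in% partition$region_id)
  bad <- bad_time | bad_region
  if (any(bad)) {
    msg <- sprintf("%d invalid event record(s): %d bad timestamp, %d unknown region",
                   sum(bad), sum(bad_time), sum(bad_region & !bad_time))
    if (strict) stop(msg)
    warning(msg)
  }
  out <- data.table::data.table(
    user_id = dt$user_id[!bad],
    tick = tick[!bad],
    day = tick_to_day(tick[!bad], calendar),
    region_id = dt$region_id[!bad])
  data.table::setorder(out, user_id, tick)
  event_table(out, rejected = sum(bad))
}

event_table <- function(dt, rejected = 0L) {
  data.table::setattr(dt, "rejected", as.integer(rejected))
  data.table::setattr(dt, "class", c("event_table", class(dt)))
  dt
}

#' Write an event table back to CSV
#'
#' Inverse of [read_events()]: emits `user_id,timestamp,region_id` with
#' ISO-8601 timestamps, so read-write-read is the identity on valid tables.
#' @param events An `event_table`.
#' @param calendar The [study_calendar()] used to decode ticks.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, calendar, path) {
  out <- data.table::data.table(
    user_id = events$user_id,
    timestamp = tick_to_timestamp(events$tick, calendar),
    region_id = events$region_id)
  data.table::fwrite(out, path)
  invisible(path)
}

#' External zone-level time series
#'
#' Container for contextual series (rainfall, vegetation index, digitized
#' income calendars, ...) already aggregated per zone: a zones x bins value
#' matrix at one of the calendar resolutions.
#'
#' @param name Series name (free text, e.g. "rainfall").
#' @param values Numeric matrix, zones in rows (rownames = zone ids), bins in
#'   columns. NA marks a missing cell.
#' @param resolution Calendar resolution of the columns.
#' @param units Free-text units.
#' @return An `external_series` object.
#' @export
external_series <- function(name, values, resolution = "monthly", units = "") {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  structure(list(name = name, values = values, resolution = resolution,
                 units = units, missing = is.na(values)),
            class = "external_series")
}

#' @export
print.external_series <- function(x, ...) {
  cat(sprintf("external_series '%s': %d zones x %d %s bins, %d missing cell(s)\n",
              x$name, nrow(x$values), ncol(x$values), x$resolution,
              sum(x$missing)))
  invisible(x)
}

#' Read an external zone-level series from CSV
#'
#' Expected columns: `zone_id,bin,value` with 1-based bin indices at the
#' declared resolution. Cells absent from the file are flagged missing (NA).
#' @param path CSV file path.
#' @param calendar A [study_calendar()].
#' @param resolution Resolution of the bin indices (default monthly).
#' @param name Series name (defaults to the file name).
#' @return An [external_series()].
#' @export
read_external_series <- function(path, calendar, resolution = "monthly",
                                 name = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("zone_id", "bin", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("series file missing columns: ",
                         paste(miss, collapse = ", "))
  nb <- n_bins(calendar, resolution)
  if (any(df$bin < 1L | df$bin > nb))
    stop("bin index outside calendar (expected 1..", nb, ")")
  zones <- sort(unique(as.character(df$zone_id)))
  m <- matrix(NA_real_, nrow = length(zones), ncol = nb,
              dimnames = list(zones, NULL))
  m[cbind(match(as.character(df$zone_id), zones), df$bin)] <- df$value
  external_series(name, m, resolution)
}

#' Write an external series to CSV (`zone_id,bin,value`; missing cells omitted)
#' @param series An [external_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_external_series <- function(series, path) {
  m <- series$values
  df <- data.frame(zone_id = rep(rownames(m), ncol(m)),
                   bin = rep(seq_len(ncol(m)), each = nrow(m)),
                   value = as.vector(m))
  df <- df[order(df$zone_id, df$bin), ]
  df <- df[!is.na(df$value), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
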