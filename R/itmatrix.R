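#' Individual trajectory matrix
#'
#' The central object of the package: an N x N_T integer matrix with one row
#' per user and one column per time bin, whose cells are 1-based region (or
#' zone) label indices; 0 is the MISSING sentinel (no activity in that bin).
#' Rows are named by user id. The attribute `labels` maps label index to the
#' region/zone identifier, `resolution` is one of daily/weekly/biweekly/
#' monthly, `level` is "region" or "zone", and `interpolated` records whether
#' missing bins have been filled.
#'
#' @param m Integer matrix (0 = missing), rownames = user ids.
#' @param labels Character vector: label index -> region/zone id.
#' @param resolution Time resolution of the columns.
#' @param level Spatial level of the labels.
#' @param interpolated Logical.
#' @param calendar The [study_calendar()] the columns refer to.
#' @return An `itmatrix`.
#' @export
itmatrix <- function(m, labels, resolution, level = c("region", "zone"),
                     interpolated = FALSE, calendar = NULL) {
  level <- match.arg(level)
  storage.mode(m) <- "integer"
  if (any(m < 0L | m > length(labels)))
    stop("itmatrix cells must be 0 (missing) or valid label indices")
  if (interpolated && any(m == 0L))
    stop("interpolated itmatrix cannot contain missing cells")
  structure(m, labels = as.character(labels), resolution = resolution,
            level = level, interpolated = interpolated, calendar = calendar,
            class = c("itmatrix", "matrix", "array"))
}

#' @export
print.itmatrix <- function(x, ...) {
  cat(sprintf("itmatrix: %d users x %d %s bins, %s level (%d labels), %s\n",
              nrow(x), ncol(x), attr(x, "resolution"), attr(x, "level"),
              length(attr(x, "labels")),
              if (attr(x, "interpolated")) "interpolated" else
                sprintf("%d missing cells", sum(x == 0L))))
  invisible(x)
}

#' Build per-user trajectory vectors from validated events
#'
#' Collapses each user's events into an ordered sequence of (tick, region)
#' visits. Exact duplicate (tick, region) pairs are collapsed to one visit;
#' two different regions at the same tick are both kept (both count as
#' visits).
#'
#' @param events An `event_table` from [read_events()].
#' @return A `trajectory_set`: data.table with columns `user_id`, `tick`,
#'   `day`, `region_id`, one row per visit, sorted by (user_id, tick).
#' @export
build_trajectories <- function(events) {
  dt <- data.table::as.data.table(events)
  dt <- unique(dt, by = c("user_id", "tick", "region_id"))
  data.table::setorder(dt, user_id, tick)
  data.table::setattr(dt, "class",
                      c("trajectory_set", class(data.table::data.table())))
  dt
}

#' Daily preferential region per user
#'
#' Regularizes irregular visit sequences to a daily series: cell (p, d) is
#' the region user p visited most often during day d (the daily preferential
#' region, the working estimate of the user's home location that day), and
#' missing (0) when the user has no visits that day. Ties are broken by the
#' region visited earliest within the day, which is deterministic and
#' independent of label ordering.
#'
#' @param trajectories A `trajectory_set` from [build_trajectories()] (an
#'   `event_table` is also accepted and collapsed first).
#' @param calendar A [study_calendar()].
#' @param partition A [region_partition()]; defines the label index space.
#' @return A daily, region-level, non-interpolated [itmatrix()].
#' @export
daily_preferential <- function(trajectories, calendar, partition) {
  if (!inherits(trajectories, "trajectory_set"))
    trajectories <- build_trajectories(trajectories)
  if (nrow(trajectories) == 0L) stop("no trajectories to regularize")
  dt <- data.table::as.data.table(trajectories)
  dt[, lab := match(region_id, partition$region_id)]
  if (anyNA(dt$lab)) stop("trajectory region not in partition")
  # visits per (user, day, region) with the first tick of that region that day
  agg <- dt[, .(nvis = .N, first_tick = min(tick)),
            by = .(user_id, day, lab)]
  # mode with earliest-visit tie-break
  data.table::setorder(agg, user_id, day, -nvis, first_tick)
  pref <- agg[, .SD[1L], by = .(user_id, day)]
  users <- sort(unique(dt$user_id))
  m <- matrix(0L, nrow = length(users), ncol = calendar$n_days,
              dimnames = list(users, NULL))
  m[cbind(match(pref$user_id, users), pref$day)] <- pref$lab
  itmatrix(m, labels = partition$region_id, resolution = "daily",
           level = "region", interpolated = FALSE, calendar = calendar)
}

#' Fill missing days with the last known position
#'
#' Every missing cell takes the value of the closest previous active day in
#' the same row; a missing run at the head of the year is filled backwards
#' with the first active day's value. Observed cells are never altered, and
#' the operation is idempotent.
#'
#' @param m A daily [itmatrix()] in which every row has at least one observed
#'   cell (rows with none are an error: such users should have been excluded
#'   upstream by the activity filter).
#' @return The interpolated [itmatrix()] (`interpolated = TRUE`, no missing
#'   cells).
#' @export
interpolate_missing <- function(m) {
  stopifnot(inherits(m, "itmatrix"))
  if (attr(m, "resolution") != "daily")
    stop("interpolation is defined on the daily matrix")
  out <- unclass(m)
  for (i in seq_len(nrow(out))) {
    x <- out[i, ]
    obs <- which(x != 0L)
    if (length(obs) == 0L)
      stop("row ", rownames(m)[i],
           " has no observed day; exclude inactive users upstream")
    if (length(obs) < length(x))
      out[i, ] <- x[obs[pmax(1L, findInterval(seq_along(x), obs))]]
  }
  itmatrix(out, labels = attr(m, "labels"), resolution = "daily",
           level = attr(m, "level"), interpolated = TRUE,
           calendar = attr(m, "calendar"))
}

# per-row mode of an integer vector (0 ignored) with earliest-position
# tie-break; returns 0 when all entries are 0
window_mode <- function(v) {
  nz <- v[v != 0L]
  if (length(nz) == 0L) return(0L)
  tab <- tabulate(nz)
  cand <- which(tab == max(tab))
  if (length(cand) == 1L) return(cand)
  # earliest first occurrence within the window wins
  cand[which.min(match(cand, v))]
}

#' Aggregate a daily trajectory matrix to a coarser time resolution
#'
#' Each coarser cell is the most frequent daily value among the bin's days
#' (missing days ignored); a cell is missing only when every day in the bin
#' is missing. Ties are broken by the value whose first day in the bin is
#' earliest. Coarser matrices are always recomputed from the daily matrix so
#' that e.g. monthly values equal the mode over the month's days.
#'
#' @param m A daily [itmatrix()].
#' @param resolution Target resolution: `"weekly"`, `"biweekly"` or
#'   `"monthly"`.
#' @param calendar A [study_calendar()] (defaults to the matrix's own).
#' @return An [itmatrix()] at the target resolution.
#' @export
aggregate_time <- function(m, resolution, calendar = attr(m, "calendar")) {
  stopifnot(inherits(m, "itmatrix"))
  if (attr(m, "resolution") != "daily")
    stop("time aggregation starts from the daily matrix")
  resolution <- match.arg(resolution, c("weekly", "biweekly", "monthly"))
  bins <- day_bins(calendar, resolution)
  nb <- max(bins)
  out <- matrix(0L, nrow = nrow(m), ncol = nb, dimnames = list(rownames(m), NULL))
  mm <- unclass(m)
  for (b in seq_len(nb)) {
    sub <- mm[, bins == b, drop = FALSE]
    out[, b] <- apply(sub, 1L, window_mode)
  }
  itmatrix(out, labels = attr(m, "labels"), resolution = resolution,
           level = attr(m, "level"), interpolated = attr(m, "interpolated"),
           calendar = calendar)
}

#' Map a region-level trajectory matrix to zone level
#'
#' Relabels every cell through the partition's region-to-zone mapping;
#' missing cells are preserved. The canonical pipeline order is time
#' regularization first, then spatial aggregation.
#'
#' @param m A region-level [itmatrix()].
#' @param partition A [region_partition()] whose `region_id`s cover the
#'   matrix labels.
#' @return A zone-level [itmatrix()] with labels `attr(partition, "zones")`.
#' @export
aggregate_space <- function(m, partition) {
  stopifnot(inherits(m, "itmatrix"))
  if (attr(m, "level") != "zone") {
    idx <- match(attr(m, "labels"), partition$region_id)
    if (anyNA(idx)) stop("matrix labels missing from partition")
    zmap <- zone_index(partition)[idx]
  } else stop("matrix is already at zone level")
  lut <- c(0L, zmap)  # 0 stays missing
  out <- matrix(lut[unclass(m) + 1L], nrow = nrow(m),
                dimnames = dimnames(m))
  itmatrix(out, labels = attr(partition, "zones"),
           resolution = attr(m, "resolution"), level = "zone",
           interpolated = attr(m, "interpolated"),
           calendar = attr(m, "calendar"))
}

#' Write / read a trajectory matrix as annotated CSV
#'
#' Plain-text serialization: `#`-prefixed header lines record resolution,
#' level, interpolation flag, calendar year and the label vocabulary; the
#' body is one row per user (`user_id` then integer labels, 0 = missing).
#' @param m An [itmatrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_itmatrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cal <- attr(m, "calendar")
  writeLines(c(
    sprintf("# resolution=%s", attr(m, "resolution")),
    sprintf("# level=%s", attr(m, "level")),
    sprintf("# interpolated=%s", attr(m, "interpolated")),
    sprintf("# year=%d", if (is.null(cal)) NA_integer_ else cal$year),
    sprintf("# labels=%s", paste(attr(m, "labels"), collapse = "|"))), con)
  utils::write.table(
    data.frame(user_id = rownames(m), unclass(m), check.names = FALSE),
    con, sep = ",", row.names = FALSE,
    col.names = c("user_id", paste0("b", seq_len(ncol(m)))), quote = FALSE)
  invisible(path)
}

#' @rdname write_itmatrix
#' @export
read_itmatrix <- function(path) {
  hdr <- readLines(path, n = 5L)
  val <- function(k) sub(sprintf("^# %s=", k), "",
                         grep(sprintf("^# %s=", k), hdr, value = TRUE))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = c(user_id = "character"))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$user_id
  colnames(m) <- NULL
  yr <- suppressWarnings(as.integer(val("year")))
  itmatrix(m, labels = strsplit(val("labels"), "|", fixed = TRUE)[[1]],
           resolution = val("resolution"), level = val("level"),
           interpolated = identical(val("interpolated"), "TRUE"),
           calendar = if (is.na(yr)) NULL else study_calendar(yr))
}
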