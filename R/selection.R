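#' Zone occupancy statistics
#'
#' For every zone, tallies how many months each user's monthly preferential
#' zone fell there, and summarizes visitors into the three canonical classes:
#' occasional visitors (exactly 1 month), moving/migratory population (2-11
#' months) and permanent residents (12 months).
#'
#' @param mpl A monthly, zone-level, interpolated [itmatrix()] (the monthly
#'   preferential zone matrix).
#' @return An `occupancy_stats` object: list with `histogram` (zones x 12
#'   matrix; column m = visitors who stayed m months) and `ratios`
#'   (data.frame `zone, visitors, occasional, moving, permanent`; the three
#'   ratios sum to 1 among visitors).
#' @export
occupancy_stats <- function(mpl) {
  stopifnot(inherits(mpl, "itmatrix"))
  if (attr(mpl, "resolution") != "monthly" || attr(mpl, "level") != "zone")
    stop("occupancy statistics are defined on the monthly zone-level matrix")
  zones <- attr(mpl, "labels")
  nz <- length(zones)
  nm <- ncol(mpl)
  hist <- matrix(0L, nrow = nz, ncol = nm,
                 dimnames = list(zones, seq_len(nm)))
  mm <- unclass(mpl)
  for (z in seq_len(nz)) {
    stayed <- rowSums(mm == z)
    stayed <- stayed[stayed > 0]
    if (length(stayed)) hist[z, ] <- tabulate(stayed, nbins = nm)
  }
  visitors <- rowSums(hist)
  ratios <- data.frame(
    zone = zones,
    visitors = as.integer(visitors),
    occasional = ifelse(visitors > 0, hist[, 1L] / visitors, NA_real_),
    moving = ifelse(visitors > 0,
                    rowSums(hist[, 2:(nm - 1L), drop = FALSE]) / visitors,
                    NA_real_),
    permanent = ifelse(visitors > 0, hist[, nm] / visitors, NA_real_),
    row.names = NULL)
  structure(list(histogram = hist, ratios = ratios),
            class = "occupancy_stats")
}

#' @export
print.occupancy_stats <- function(x, ...) {
  cat("occupancy_stats:\n")
  print(x$ratios, digits = 3)
  invisible(x)
}

KM_PER_DEG <- 111.19493  # mean earth radius 6371 km * pi / 180

# project centroids to a local planar frame (km) around reference lat/lon
local_planar_km <- function(lat, lon, lat0, lon0) {
  cbind(x = (lon - lon0) * KM_PER_DEG * cos(lat0 * pi / 180),
        y = (lat - lat0) * KM_PER_DEG)
}

#' Radius of gyration of a daily trajectory
#'
#' The root-mean-square distance (km) of a user's daily positions from their
#' visit-weighted mean position — the scale of the user's typical movement.
#' Positions are region centroids; each day carries equal weight; distances
#' are computed in a local planar approximation around the weighted mean.
#'
#' @param row Integer vector of daily region label indices (an interpolated
#'   daily `itmatrix` row; 0 entries are ignored).
#' @param partition The [region_partition()] providing centroids.
#' @return Radius of gyration in km (0 for a user seen in a single region).
#' @export
radius_of_gyration <- function(row, partition) {
  row <- row[row != 0L]
  if (length(row) == 0L) return(0)
  w <- tabulate(row, nbins = nrow(partition))
  used <- which(w > 0L)
  if (length(used) == 1L) return(0)
  wts <- w[used] / sum(w[used])
  lat0 <- sum(wts * partition$lat[used])
  lon0 <- sum(wts * partition$lon[used])
  xy <- local_planar_km(partition$lat[used], partition$lon[used], lat0, lon0)
  ctr <- c(sum(wts * xy[, 1]), sum(wts * xy[, 2]))
  sqrt(sum(wts * ((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)))
}

#' Radii of gyration for every row of a daily matrix
#' @param m A daily region-level [itmatrix()].
#' @inheritParams radius_of_gyration
#' @return Named numeric vector of radii (km), one per user.
#' @export
radii_of_gyration <- function(m, partition) {
  stopifnot(inherits(m, "itmatrix"), attr(m, "level") == "region")
  r <- apply(unclass(m), 1L, radius_of_gyration, partition = partition)
  names(r) <- rownames(m)
  r
}

#' Flag regular travelers
#'
#' A user is a "regular traveler" when no day-to-day region change covers a
#' centroid distance exceeding `ratio_threshold` times their radius of
#' gyration, i.e. their moves stay within the scale of their routine
#' mobility. Such users are removed when hunting for unusual (migratory)
#' displacements. Day-to-day move distances are great-circle (haversine)
#' distances between region centroids. A user with no moves is regular; a
#' user with zero radius of gyration but some move is not.
#'
#' @param m A daily region-level [itmatrix()] (interpolated recommended, so
#'   moves are observable every day).
#' @param partition The [region_partition()].
#' @param ratio_threshold Move-distance to radius-of-gyration ratio (default
#'   3).
#' @return Named logical vector: `TRUE` = regular traveler.
#' @export
flag_regular_travelers <- function(m, partition, ratio_threshold = 3) {
  stopifnot(inherits(m, "itmatrix"), attr(m, "level") == "region")
  rg <- radii_of_gyration(m, partition)
  mm <- unclass(m)
  maxmove <- vapply(seq_len(nrow(mm)), function(i) {
    x <- mm[i, ]
    x <- x[x != 0L]
    if (length(x) < 2L) return(0)
    a <- x[-length(x)]; b <- x[-1L]
    ch <- which(a != b)
    if (length(ch) == 0L) return(0)
    max(geosphere::distHaversine(
      cbind(partition$lon[a[ch]], partition$lat[a[ch]]),
      cbind(partition$lon[b[ch]], partition$lat[b[ch]])) / 1000)
  }, numeric(1))
  out <- maxmove <= ratio_threshold * rg
  names(out) <- rownames(m)
  out
}

#' Selection configuration for a target zone
#'
#' Bundles the filtering constraints applied when selecting candidate
#' seasonal migrants for one target zone: the four temporal constraints
#' (minimum consecutive months in the target, maximum total months in the
#' target, minimum months in some other zone, and an optional required
#' period), plus the regular-traveler ratio threshold and the urban and
#' non-moving exclusions.
#'
#' @param target_zone Zone id (must match a partition zone label).
#' @param min_consecutive_months Minimum length of the longest consecutive
#'   run of months in the target zone (default 2). Consecutive is
#'   non-wrapping (December to January does not continue a run).
#' @param max_months Maximum total months in the target zone (default 11;
#'   12 would admit permanent residents).
#' @param min_months_elsewhere Minimum months spent in a single other zone
#'   (default 1); set `elsewhere_mode = "sum"` to count all other zones
#'   together.
#' @param required_period Optional integer vector of months (1-12) during
#'   all of which the user must be in the target zone.
#' @param rog_ratio_threshold Regular-traveler ratio (default 3).
#' @param exclude_urban Drop users permanently resident in urban-flagged
#'   regions (default FALSE).
#' @param exclude_nonmoving Drop users spending all 12 months in the target
#'   zone (default TRUE).
#' @param elsewhere_mode `"max"` (single other zone, default) or `"sum"`.
#' @return A `selection_config` list.
#' @export
selection_config <- function(target_zone,
                             min_consecutive_months = 2L,
                             max_months = 11L,
                             min_months_elsewhere = 1L,
                             required_period = NULL,
                             rog_ratio_threshold = 3,
                             exclude_urban = FALSE,
                             exclude_nonmoving = TRUE,
                             elsewhere_mode = c("max", "sum")) {
  elsewhere_mode <- match.arg(elsewhere_mode)
  if (min_consecutive_months < 1L || min_consecutive_months > max_months ||
      max_months > 12L)
    stop("need 1 <= min_consecutive_months <= max_months <= 12")
  if (rog_ratio_threshold <= 0) stop("rog_ratio_threshold must be positive")
  if (!is.null(required_period) &&
      (any(required_period < 1L) || any(required_period > 12L)))
    stop("required_period months must be in 1..12")
  structure(list(target_zone = as.character(target_zone),
                 min_consecutive_months = as.integer(min_consecutive_months),
                 max_months = as.integer(max_months),
                 min_months_elsewhere = as.integer(min_months_elsewhere),
                 required_period = required_period,
                 rog_ratio_threshold = rog_ratio_threshold,
                 exclude_urban = exclude_urban,
                 exclude_nonmoving = exclude_nonmoving,
                 elsewhere_mode = elsewhere_mode),
            class = "selection_config")
}

# longest run of TRUE in a logical vector (non-wrapping)
longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Select candidate migrants for a target zone
#'
#' Applies the selection stages in a fixed order, reporting the users removed
#' at each stage so the share of discarded population is auditable:
#' (1) visited the target zone at least one month; (2) not resident there all
#' 12 months (when `exclude_nonmoving`); (3) not a regular traveler;
#' (4) not permanently resident in an urban-flagged region (when
#' `exclude_urban`; the residence region is the user's most-occupied daily
#' region); (5) longest consecutive run of months in the target meets the
#' minimum; (6) total months in the target within the maximum; (7) enough
#' months in some other zone; (8) present in the target during the required
#' period, if one is set.
#'
#' @param mpl Monthly zone-level interpolated [itmatrix()].
#' @param daily Daily region-level [itmatrix()] over the same users
#'   (interpolated), used for the radius-of-gyration and residence checks.
#' @param partition The [region_partition()].
#' @param cfg A [selection_config()].
#' @return List with `selected` (character user ids) and `audit` (data.frame
#'   `stage, removed, remaining`).
#' @export
select_users <- function(mpl, daily, partition, cfg) {
  stopifnot(inherits(cfg, "selection_config"))
  if (!identical(rownames(mpl), rownames(daily)))
    stop("monthly and daily matrices must cover the same users in order")
  zones <- attr(mpl, "labels")
  zt <- match(cfg$target_zone, zones)
  if (is.na(zt)) stop("target zone ", cfg$target_zone, " not in partition")
  mm <- unclass(mpl)
  months_in_target <- rowSums(mm == zt)

  audit <- data.frame(stage = character(), removed = integer(),
                      remaining = integer())
  keep <- months_in_target >= 1L
  audit <- rbind(audit, data.frame(stage = "visited_target",
                                   removed = sum(!keep),
                                   remaining = sum(keep)))
  log_stage <- function(name, drop) {
    removed <- sum(keep & drop)
    keep <<- keep & !drop
    audit <<- rbind(audit, data.frame(stage = name, removed = removed,
                                      remaining = sum(keep)))
  }
  if (cfg$exclude_nonmoving)
    log_stage("nonmoving", months_in_target == ncol(mm))
  regular <- flag_regular_travelers(daily, partition,
                                    cfg$rog_ratio_threshold)
  log_stage("regular_traveler", regular)
  if (cfg$exclude_urban) {
    home_region <- apply(unclass(daily), 1L, window_mode)
    urban_res <- partition$urban[home_region]
    urban_res[is.na(urban_res)] <- FALSE
    log_stage("urban_resident", urban_res)
  }
  runs <- apply(mm == zt, 1L, longest_run)
  log_stage("min_consecutive", runs < cfg$min_consecutive_months)
  log_stage("max_months", months_in_target > cfg$max_months)
  other <- mm
  other[other == zt] <- 0L
  elsewhere <- if (cfg$elsewhere_mode == "max") {
    vapply(seq_len(nrow(other)), function(i) {
      x <- other[i, ][other[i, ] != 0L]
      if (length(x) == 0L) 0L else max(tabulate(x, nbins = length(zones)))
    }, integer(1))
  } else rowSums(other != 0L)
  log_stage("min_elsewhere", elsewhere < cfg$min_months_elsewhere)
  if (!is.null(cfg$required_period))
    log_stage("required_period",
              rowSums(mm[, cfg$required_period, drop = FALSE] == zt) <
                length(cfg$required_period))
  selected <- rownames(mpl)[keep]
  if (length(selected) == 0L)
    warning("no users survived selection for zone ", cfg$target_zone)
  list(selected = selected, audit = audit)
}

#' Binarize monthly zone profiles for a target zone
#'
#' Reduces each selected user's monthly preferential-zone row to a 0/1 vector
#' indicating, month by month, whether the user was in the target zone. Rows
#' must contain at least one 1 (the selection contract guarantees a visit).
#'
#' @param mpl Monthly zone-level [itmatrix()].
#' @param users Character vector of selected user ids (rows of `mpl`).
#' @param target_zone Zone id.
#' @return A `binary_profiles` 0/1 integer matrix, users x months.
#' @export
binarize <- function(mpl, users, target_zone) {
  if (length(users) == 0L) stop("no users to binarize")
  zt <- match(as.character(target_zone), attr(mpl, "labels"))
  if (is.na(zt)) stop("target zone not in matrix labels")
  miss <- setdiff(users, rownames(mpl))
  if (length(miss)) stop("users not in matrix: ", paste(miss, collapse = ", "))
  B <- (unclass(mpl)[users, , drop = FALSE] == zt) * 1L
  if (any(rowSums(B) == 0L))
    stop("selection contract violated: user(s) never in target zone: ",
         paste(users[rowSums(B) == 0L], collapse = ", "))
  structure(B, target_zone = as.character(target_zone),
            class = c("binary_profiles", "matrix", "array"))
}
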