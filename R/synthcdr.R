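#' Synthetic region partition
#'
#' Deterministic Senegal-like geography: `n_zones` zone centers on a grid
#' over a west-African bounding box, with `n_regions` regions dealt
#' round-robin to zones and their centroids placed on a small spiral around
#' the zone center (so within-zone moves are short and between-zone moves are
#' long). Zone "1" is flagged urban, standing in for the capital; defaults
#' mirror the 123-region / 13-zone administrative layout the package is
#' designed around.
#'
#' @param n_regions Number of regions (default 123).
#' @param n_zones Number of zones (default 13).
#' @param urban_zones Zone labels flagged urban (default "1").
#' @return A [region_partition()].
#' @export
synthetic_partition <- function(n_regions = 123L, n_zones = 13L,
                                urban_zones = "1") {
  if (n_zones > n_regions) stop("need at least one region per zone")
  grid_n <- ceiling(sqrt(n_zones))
  zi <- seq_len(n_zones) - 1L
  zone_lat <- 12.5 + 4 * (zi %/% grid_n) / max(1L, grid_n - 1L)
  zone_lon <- -17.5 + 5 * (zi %% grid_n) / max(1L, grid_n - 1L)
  zone_of <- rep(seq_len(n_zones), length.out = n_regions)
  within <- ave(seq_len(n_regions), zone_of, FUN = seq_along)
  # golden-angle spiral: deterministic sub-degree jitter around the center
  ang <- within * 2.399963
  rad <- 0.05 * sqrt(within)
  region_partition(
    region_id = sprintf("R%03d", seq_len(n_regions)),
    lat = zone_lat[zone_of] + rad * sin(ang),
    lon = zone_lon[zone_of] + rad * cos(ang),
    zone_id = as.character(zone_of),
    urban = as.character(zone_of) %in% as.character(urban_zones))
}

#' Behavioral group specifications
#'
#' Itinerary templates for the planted mobility behaviors: permanent
#' residents stay in the home zone all year; occasional visitors spend a
#' single month in a visit zone; seasonal migrants live in the destination
#' zone from the departure month until the month before the return month.
#'
#' @param size Number of users in the group.
#' @param home_zone,visit_zone,dest_zone Zone labels (must exist in the
#'   scenario partition).
#' @param visit_month Month (1-12) of the occasional visit.
#' @param depart_month,return_month Departure and return months of the
#'   seasonal migration (months `depart..return-1` are spent away).
#' @param name Optional group name.
#' @return A `group_spec` list.
#' @export
group_permanent <- function(size, home_zone, name = "permanent") {
  structure(list(type = "permanent", size = as.integer(size),
                 home_zone = as.character(home_zone), name = name),
            class = "group_spec")
}

#' @rdname group_permanent
#' @export
group_occasional <- function(size, home_zone, visit_zone, visit_month,
                             name = "occasional") {
  stopifnot(visit_month >= 1L, visit_month <= 12L)
  structure(list(type = "occasional", size = as.integer(size),
                 home_zone = as.character(home_zone),
                 visit_zone = as.character(visit_zone),
                 visit_month = as.integer(visit_month), name = name),
            class = "group_spec")
}

#' @rdname group_permanent
#' @export
group_seasonal <- function(size, home_zone, dest_zone, depart_month,
                           return_month, name = "seasonal") {
  stopifnot(depart_month >= 1L, return_month <= 13L,
            depart_month < return_month)
  structure(list(type = "seasonal", size = as.integer(size),
                 home_zone = as.character(home_zone),
                 dest_zone = as.character(dest_zone),
                 depart_month = as.integer(depart_month),
                 return_month = as.integer(return_month), name = name),
            class = "group_spec")
}

monthly_zones_for_group <- function(g) {
  z <- rep(g$home_zone, 12L)
  if (g$type == "occasional") z[g$visit_month] <- g$visit_zone
  if (g$type == "seasonal")
    z[g$depart_month:(g$return_month - 1L)] <- g$dest_zone
  z
}

#' Scenario specification for the synthetic CDR generator
#'
#' Bundles the study conditions the generator emulates: a fixed calendar
#' year, a region partition grouped into zones, behavioral user groups, and
#' the call-activity model. Defaults reproduce the operating regime of
#' year-long operator exports: 10-minute time quantization, a mean of 4 calls
#' per active day, a 0.2 daily inactivity probability (about 292 active
#' days), and a 256-day minimum-activity floor matching the activity filter
#' such datasets ship with.
#'
#' @param groups List of [group_permanent()]/[group_occasional()]/
#'   [group_seasonal()] specs.
#' @param partition A [region_partition()] (default [synthetic_partition()]).
#' @param year Study year (default 2013).
#' @param lambda Mean calls per active day (every active day has >= 1 call).
#' @param inactivity Per-day probability of no phone activity.
#' @param min_active_days Activity floor; inactive users are topped up to it.
#' @param flip_noise Per-cell flip probability used when planting binary
#'   profiles directly (see [generate_binary_profiles()]).
#' @param rain_onset_month,rain_peak_month Onset (first month at half peak)
#'   and peak of the synthetic rainfall bump.
#' @param rural_zones Zone labels receiving the rainfall seasonality; others
#'   get a flat low series. Default: every non-urban zone.
#' @param seed RNG seed; all sampling is drawn from one stream in a fixed
#'   order, so outputs are reproducible byte for byte.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(groups, partition = synthetic_partition(),
                          year = 2013L, lambda = 4, inactivity = 0.2,
                          min_active_days = 256L, flip_noise = 0.05,
                          rain_onset_month = 6L, rain_peak_month = 8L,
                          rural_zones = NULL, seed = 1L) {
  stopifnot(length(groups) >= 1L,
            all(vapply(groups, inherits, logical(1), "group_spec")))
  if (inactivity < 0 || inactivity > 1) stop("inactivity must be in [0,1]")
  if (flip_noise < 0 || flip_noise > 1) stop("flip_noise must be in [0,1]")
  cal <- study_calendar(year)
  if (min_active_days > cal$n_days)
    stop("min_active_days exceeds the calendar length")
  zones <- attr(partition, "zones")
  for (g in groups) {
    gz <- unique(monthly_zones_for_group(g))
    if (!all(gz %in% zones))
      stop("group '", g$name, "' references zone(s) outside the partition: ",
           paste(setdiff(gz, zones), collapse = ", "))
    if (g$size < 0L) stop("group sizes must be >= 0")
  }
  if (is.null(rural_zones)) {
    urb <- unique(partition$zone_id[partition$urban])
    rural_zones <- setdiff(zones, urb)
  }
  structure(list(groups = groups, partition = partition, year = year,
                 calendar = cal, lambda = lambda, inactivity = inactivity,
                 min_active_days = as.integer(min_active_days),
                 flip_noise = flip_noise,
                 rain_onset_month = as.integer(rain_onset_month),
                 rain_peak_month = as.integer(rain_peak_month),
                 rural_zones = as.character(rural_zones),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Generate a synthetic CDR scenario
#'
#' Draws, from a single seeded RNG stream and in a fixed order (per user:
#' monthly region choices, daily activity, per-day call counts, call ticks),
#' the full synthetic dataset: validated call events, planted ground truth,
#' and a synthetic monthly rainfall series whose onset (half-peak crossing)
#' falls at the configured month in rural zones. Each user's true zone per month
#' follows their group itinerary; their region within that zone is drawn
#' uniformly per month and held fixed for the month; calls land on uniformly
#' random 10-minute ticks of active days.
#'
#' @param spec A [scenario_spec()].
#' @return List with `events` (event_table), `truth` (list: `users`
#'   data.frame of user/group, `monthly_zone` users x 12 zone-label matrix,
#'   `daily_region` users x days region-label matrix, `occupancy` zones x 12
#'   planted count matrix), `partition`, `rainfall` ([external_series()]),
#'   `calendar`, and `spec`.
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  part <- spec$partition
  cal <- spec$calendar
  nd <- cal$n_days
  mo <- day_bins(cal, "monthly")
  zones <- attr(part, "zones")
  regions_of_zone <- split(seq_len(nrow(part)), part$zone_id)

  sizes <- vapply(spec$groups, `[[`, integer(1), "size")
  n <- sum(sizes)
  if (n == 0L) stop("scenario has no users")
  user_id <- sprintf("u%05d", seq_len(n))
  group <- rep(vapply(spec$groups, `[[`, character(1), "name"), sizes)

  ztmpl <- vapply(spec$groups, monthly_zones_for_group, character(12L))
  monthly_zone <- t(ztmpl)[rep(seq_along(spec$groups), sizes), , drop = FALSE]
  rownames(monthly_zone) <- user_id

  daily_region <- matrix(0L, n, nd, dimnames = list(user_id, NULL))
  ev <- vector("list", n)
  for (u in seq_len(n)) {
    # region per month: uniform within the month's zone, fixed for the month
    reg_m <- vapply(monthly_zone[u, ], function(z) {
      cand <- regions_of_zone[[z]]
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    dr <- reg_m[mo]
    daily_region[u, ] <- dr
    active <- stats::runif(nd) >= spec$inactivity
    short <- spec$min_active_days - sum(active)
    if (short > 0L) {
      idle <- which(!active)
      active[idle[sample.int(length(idle), short)]] <- TRUE
    }
    days <- which(active)
    ncall <- 1L + stats::rpois(length(days), max(0, spec$lambda - 1))
    day_rep <- rep(days, ncall)
    tick <- (day_rep - 1L) * TICKS_PER_DAY +
      sample.int(TICKS_PER_DAY, sum(ncall), replace = TRUE) - 1L
    ev[[u]] <- data.table::data.table(
      user_id = user_id[u], tick = tick, day = day_rep,
      region_id = part$region_id[dr[day_rep]])
  }
  events <- data.table::rbindlist(ev)
  data.table::setorder(events, user_id, tick)
  events <- event_table(events, rejected = 0L)

  occupancy <- vapply(seq_len(12L), function(m)
    as.integer(table(factor(monthly_zone[, m], levels = zones))),
    integer(length(zones)))
  rownames(occupancy) <- zones

  rain <- synthetic_rainfall(zones, spec$rural_zones,
                             spec$rain_onset_month, spec$rain_peak_month)
  list(events = events,
       truth = list(users = data.frame(user_id = user_id, group = group,
                                       stringsAsFactors = FALSE),
                    monthly_zone = monthly_zone,
                    daily_region = matrix(part$region_id[daily_region], n, nd,
                                          dimnames = list(user_id, NULL)),
                    occupancy = occupancy),
       partition = part, rainfall = rain, calendar = cal, spec = spec)
}

# gaussian rainfall bump whose half-peak crossing is exactly the onset month
synthetic_rainfall <- function(zones, rural_zones, onset, peak) {
  s <- (peak - onset) / sqrt(log(2))
  bump <- exp(-((seq_len(12L) - peak) / s)^2)
  m <- matrix(0.05, nrow = length(zones), ncol = 12L,
              dimnames = list(zones, NULL))
  m[rural_zones, ] <- rep(100 * bump, each = length(rural_zones))
  external_series("rainfall", m, "monthly", units = "mm")
}

#' Plant noisy binary occupancy profiles
#'
#' Draws group-structured 0/1 monthly profiles directly: each user copies
#' their group's 12-month template and every cell is flipped independently
#' with probability `flip_noise`. A row that degenerates to all zeros (no
#' Jaccard distance is defined for it) has its noise redrawn.
#'
#' @param templates k x 12 0/1 matrix of group templates.
#' @param sizes Integer vector of group sizes (length k).
#' @param flip_noise Per-cell flip probability.
#' @param seed Optional seed (uses the current RNG stream when NULL).
#' @return List with `B` (a `binary_profiles` matrix) and `labels` (true
#'   group per row).
#' @export
generate_binary_profiles <- function(templates, sizes, flip_noise = 0.05,
                                     seed = NULL) {
  stopifnot(is.matrix(templates), length(sizes) == nrow(templates))
  if (!is.null(seed)) set.seed(seed)
  labels <- rep(seq_along(sizes), sizes)
  B <- templates[labels, , drop = FALSE]
  flips <- matrix(stats::runif(length(B)) < flip_noise, nrow(B), ncol(B))
  B <- (B + flips) %% 2L
  degenerate <- which(rowSums(B) == 0L)
  for (i in degenerate) {
    repeat {
      row <- (templates[labels[i], ] +
                (stats::runif(ncol(B)) < flip_noise)) %% 2L
      if (sum(row) > 0L) break
    }
    B[i, ] <- row
  }
  rownames(B) <- sprintf("u%05d", seq_len(nrow(B)))
  storage.mode(B) <- "integer"
  list(B = structure(B, class = c("binary_profiles", "matrix", "array")),
       labels = labels)
}

#' Canonical planted seasonal profile templates
#'
#' Three 12-month 0/1 occupancy templates used as the default planted
#' mobility profiles: dry-season residents (in the zone January-June), a
#' rainy-season workforce (May-October) and harvest/holiday visitors
#' (September-February). The six-month windows overlap by two months on a
#' ring, so every pair of templates keeps a large but non-saturated Jaccard
#' distance (5/6 rather than exactly 1). Keeping distances strictly below 1
#' matters numerically: with fully disjoint supports most between-group
#' distances equal 1 exactly, agglomeration heights saturate, and the
#' dendrogram cut degenerates into tie-order artifacts under complete
#' linkage.
#'
#' @return 3 x 12 integer 0/1 matrix.
#' @export
seasonal_profile_templates <- function() {
  rbind(c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
        c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 0, 0),
        c(1, 1, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1))
}

#' Write a generated scenario to disk
#'
#' Emits the scenario in the package's file dialects: `events.csv`
#' (`user_id,timestamp,region_id`), `partition.csv`, `rainfall.csv`
#' (`zone_id,bin,value`) and `truth.csv` (one row per user-day:
#' `user_id,day,region_id,zone_id,group`). Outputs are byte-identical across
#' runs with the same seed.
#'
#' @param gen Output of [generate_scenario()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of file paths.
#' @export
emit_files <- function(gen, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir)
  paths <- c(events = file.path(dir, "events.csv"),
             partition = file.path(dir, "partition.csv"),
             rainfall = file.path(dir, "rainfall.csv"),
             truth = file.path(dir, "truth.csv"))
  write_events(gen$events, gen$calendar, paths[["events"]])
  write_partition(gen$partition, paths[["partition"]])
  write_external_series(gen$rainfall, paths[["rainfall"]])
  nd <- gen$calendar$n_days
  users <- gen$truth$users
  mo <- day_bins(gen$calendar, "monthly")
  truth <- data.table::data.table(
    user_id = rep(users$user_id, each = nd),
    day = rep(seq_len(nd), nrow(users)),
    region_id = as.vector(t(gen$truth$daily_region)),
    zone_id = as.vector(t(gen$truth$monthly_zone[, mo, drop = FALSE])),
    group = rep(users$group, each = nd))
  data.table::fwrite(truth, paths[["truth"]])
  paths
}
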