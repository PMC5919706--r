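# Independent brute-force oracles and small fixture builders.
# The oracles are deliberately written as plain record-by-record loops so
# they share no code path with the package implementations they check.

# mode of the visits of one user on one day: most frequent region, ties
# broken by the region seen earliest that day; NA when no visits
oracle_day_mode <- function(ticks, regions) {
  if (length(ticks) == 0L) return(NA_character_)
  regs <- unique(regions[order(ticks)])
  best <- NA_character_
  best_n <- -1L
  for (r in regs) {  # regs ordered by first appearance
    n <- sum(regions == r)
    if (n > best_n) {
      best <- r
      best_n <- n
    }
  }
  best
}

# mode over a window of daily labels (0 = missing), ties by earliest day
oracle_window_mode <- function(v) {
  v <- as.integer(v)
  seen <- integer(0)
  for (x in v) if (x != 0L && !(x %in% seen)) seen <- c(seen, x)
  if (length(seen) == 0L) return(0L)
  best <- 0L
  best_n <- -1L
  for (s in seen) {
    n <- sum(v == s)
    if (n > best_n) {
      best <- s
      best_n <- n
    }
  }
  best
}

# random event set for <= max_users users x <= max_days days, possibly with
# empty days and deliberate tie situations (few regions, few ticks per day)
random_event_instance <- function(max_users = 10L, max_days = 31L,
                                  n_regions = 4L) {
  nu <- sample.int(max_users, 1L)
  nd <- sample.int(max_days, 1L)
  rows <- list()
  for (u in seq_len(nu)) {
    for (d in seq_len(nd)) {
      k <- sample(0:4, 1L)
      if (k == 0L) next
      ticks <- sort(sample.int(144L, k, replace = TRUE)) - 1L + (d - 1L) * 144L
      rows[[length(rows) + 1L]] <- data.frame(
        user_id = sprintf("u%02d", u), tick = ticks, day = d,
        region_id = sprintf("R%03d", sample.int(n_regions, k, replace = TRUE)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

# partition with n regions on a tiny grid, nz zones
toy_partition <- function(n = 4L, nz = 2L, urban = NULL) {
  region_partition(sprintf("R%03d", seq_len(n)),
                   lat = 14 + 0.1 * seq_len(n),
                   lon = -16 + 0.1 * seq_len(n),
                   zone_id = as.character(rep(seq_len(nz), length.out = n)),
                   urban = urban)
}

# hand-built monthly zone-level matrix from a list of 12-long label rows
toy_mpl <- function(rows, zones, calendar = study_calendar(2013)) {
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("u%02d", seq_along(rows))
  itmatrix(m, labels = zones, resolution = "monthly", level = "zone",
           interpolated = TRUE, calendar = calendar)
}

# partition whose two regions sit a known haversine distance apart (km),
# on the equator so planar and great-circle distances agree closely
two_point_partition <- function(dist_km = 10) {
  dlon <- dist_km / 111.19493
  region_partition(c("A", "B"), lat = c(0, 0), lon = c(0, dlon),
                   zone_id = c("1", "2"))
}

# standard mini scenario used across tests: permanent + 1-month seasonal +
# occasional visitors of zone "3" in a 12-region / 4-zone geography
mini_scenario <- function(n_perm = 30L, n_seas = 20L, n_occ = 10L,
                          seed = 42L) {
  part <- synthetic_partition(n_regions = 12L, n_zones = 4L)
  scenario_spec(
    groups = list(
      group_permanent(n_perm, "3"),
      group_seasonal(n_seas, "3", "1", depart_month = 6L, return_month = 7L),
      group_occasional(n_occ, "2", "3", visit_month = 4L)),
    partition = part, seed = seed)
}
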