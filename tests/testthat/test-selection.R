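cal <- study_calendar(2013)

test_that("occupancy statistics classify visitors by months stayed", {
  zones <- c("z1", "z2", "z3")
  mpl <- toy_mpl(list(
    rep(1L, 12),                      # permanent in z1
    c(rep(1L, 11), 2L),               # 11 months z1 (moving), 1 month z2
    c(rep(2L, 6), rep(3L, 6))), zones)
  os <- occupancy_stats(mpl)
  expect_equal(unname(os$histogram["z1", 12]), 1L)
  expect_equal(unname(os$histogram["z1", 11]), 1L)
  expect_equal(unname(os$histogram["z2", 1]), 1L)   # occasional visitor
  r1 <- os$ratios[os$ratios$zone == "z1", ]
  expect_equal(r1$visitors, 2L)
  expect_equal(r1$permanent, 0.5)
  expect_equal(r1$moving, 0.5)
  # class partition: ratios sum to 1 for every visited zone
  with_vis <- os$ratios[os$ratios$visitors > 0, ]
  expect_equal(with_vis$occasional + with_vis$moving + with_vis$permanent,
               rep(1, nrow(with_vis)), tolerance = 1e-12)
  expect_equal(rowSums(os$histogram), c(z1 = 2, z2 = 2, z3 = 1))
})

test_that("planted occupancy fractions are recovered from a seeded scenario", {
  g <- generate_scenario(mini_scenario(25, 20, 5, seed = 12))
  daily <- interpolate_missing(
    daily_preferential(build_trajectories(g$events), g$calendar, g$partition))
  mpl <- aggregate_space(aggregate_time(daily, "monthly"), g$partition)
  os <- occupancy_stats(mpl)
  r <- os$ratios[os$ratios$zone == "3", ]
  # zone 3 visitors: 25 permanent, 20 seasonal residents (11 months ->
  # moving), 5 occasional visitors
  expect_equal(r$visitors, 50L)
  expect_equal(r$permanent, 0.5)
  expect_equal(r$moving, 0.4)
  expect_equal(r$occasional, 0.1)
})

test_that("radius of gyration is zero for a sedentary user and exact for two sites", {
  part <- two_point_partition(10)
  stay <- rep(1L, 365)
  expect_equal(radius_of_gyration(stay, part), 0)
  # equal time split between centroids 10 km apart -> rg = 5 km
  alt <- rep(c(1L, 2L), length.out = 366)[1:366]
  expect_equal(radius_of_gyration(alt[1:366], part), 5, tolerance = 1e-3)
  # uneven split: rg = D * sqrt(w1 * w2)
  f <- 1 / 3
  uneven <- c(rep(1L, 244), rep(2L, 122))
  expect_equal(radius_of_gyration(uneven, part),
               10 * sqrt(f * (1 - f)), tolerance = 1e-2)
})

test_that("radius of gyration never exceeds the span of visited centroids", {
  set.seed(21)
  part <- synthetic_partition(12, 4)
  xy <- cbind(part$lon, part$lat)
  for (i in 1:30) {
    row <- sample(1:12, 365, replace = TRUE)
    rg <- radius_of_gyration(row, part)
    used <- unique(row)
    dmax <- max(geosphere::distHaversine(
      xy[rep(used, each = length(used)), , drop = FALSE],
      xy[rep(used, length(used)), , drop = FALSE])) / 1000
    expect_lte(rg, dmax + 1e-6)
  }
})

test_that("regular travelers are flagged by the move-to-gyration ratio", {
  part <- two_point_partition(100)
  cal1 <- study_calendar(2013)
  mk <- function(row) itmatrix(rbind(u1 = as.integer(row)),
                               labels = part$region_id, resolution = "daily",
                               interpolated = TRUE, calendar = cal1)
  # non-mover: max move 0 -> regular
  expect_true(flag_regular_travelers(mk(rep(1L, 365)), part, 3)[["u1"]])
  # one long 100 km move late in the year: rg stays small, 100 > 3 * rg
  row <- c(rep(1L, 358), rep(2L, 7))
  rg <- radius_of_gyration(row, part)
  expect_lt(3 * rg, 100)
  expect_false(flag_regular_travelers(mk(row), part, 3)[["u1"]])
  # frequent small-scale alternation: every move within the ratio -> regular
  row2 <- rep(c(1L, 2L), length.out = 365)
  expect_true(flag_regular_travelers(mk(row2), part, 3)[["u1"]])
})

test_that("the regular-traveler flag is scale-invariant", {
  # multiplying all mutual distances by c scales both the moves and the
  # radius of gyration, leaving the comparison unchanged
  for (scale in c(0.25, 1, 4)) {
    part <- two_point_partition(40 * scale)
    row <- c(rep(1L, 300), rep(2L, 65))
    m <- itmatrix(rbind(u1 = as.integer(row)), labels = part$region_id,
                  resolution = "daily", interpolated = TRUE, calendar = cal)
    expect_true(flag_regular_travelers(m, part, 3)[["u1"]])
    row2 <- c(rep(1L, 358), rep(2L, 7))
    m2 <- itmatrix(rbind(u1 = as.integer(row2)), labels = part$region_id,
                   resolution = "daily", interpolated = TRUE, calendar = cal)
    expect_false(flag_regular_travelers(m2, part, 3)[["u1"]])
  }
})

test_that("selection applies its stages in order with a faithful audit", {
  part <- synthetic_partition(8, 4)
  zones <- attr(part, "zones")
  # daily matrix: everyone sedentary in a region of their monthly zone
  mk_daily <- function(zrows) {
    mo <- day_bins(cal, "monthly")
    rows <- t(vapply(zrows, function(zr) {
      reg <- match(part$zone_id, zones)  # first region of each zone
      first_region <- vapply(zr, function(z) which(reg == z)[1], integer(1))
      first_region[mo]
    }, integer(365)))
    rownames(rows) <- sprintf("u%02d", seq_along(zrows))
    itmatrix(rows, labels = part$region_id, resolution = "daily",
             interpolated = TRUE, calendar = cal)
  }
  zrows <- list(
    rep(1L, 12),                                  # nonmoving in target
    c(rep(1L, 3), rep(2L, 9)),                    # 3 consec target + 9 elsewhere
    c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L),  # runs of 1 only
    rep(3L, 12))                                  # never in target
  mpl <- toy_mpl(lapply(zrows, as.integer), zones)
  daily <- mk_daily(zrows)
  cfg <- selection_config("1", min_consecutive_months = 2, max_months = 11,
                          min_months_elsewhere = 2, rog_ratio_threshold = 0.5)
  sel <- select_users(mpl, daily, part, cfg)
  expect_equal(sel$selected, "u02")
  a <- sel$audit
  expect_equal(a$removed[a$stage == "visited_target"], 1L)  # u04
  expect_equal(a$removed[a$stage == "nonmoving"], 1L)       # u01
  expect_equal(a$removed[a$stage == "min_consecutive"], 1L) # u03
  # audit removals account for every visitor not selected
  visitors <- sum(rowSums(unclass(mpl) == 1L) > 0)
  expect_equal(sum(a$removed[a$stage != "visited_target"]),
               visitors - length(sel$selected))
  # required-period constraint
  cfg2 <- selection_config("1", min_consecutive_months = 2,
                           required_period = c(1L, 2L),
                           rog_ratio_threshold = 0.5)
  sel2 <- select_users(mpl, daily, part, cfg2)
  expect_equal(sel2$selected, "u02")
  cfg3 <- selection_config("1", min_consecutive_months = 2,
                           required_period = c(6L, 7L),
                           rog_ratio_threshold = 0.5)
  expect_warning(sel3 <- select_users(mpl, daily, part, cfg3), "no users")
  expect_equal(length(sel3$selected), 0L)
})

test_that("planted migrants are selected and permanents and urbans are not", {
  g <- generate_scenario(mini_scenario(30, 20, 10, seed = 52))
  daily <- interpolate_missing(
    daily_preferential(build_trajectories(g$events), g$calendar, g$partition))
  mpl <- aggregate_space(aggregate_time(daily, "monthly"), g$partition)
  sel <- select_users(mpl, daily, g$partition, selection_config("3"))
  grp <- g$truth$users$group[match(sel$selected, g$truth$users$user_id)]
  n_seasonal <- sum(g$truth$users$group == "seasonal")
  expect_gte(sum(grp == "seasonal") / n_seasonal, 0.95)
  expect_equal(sum(grp == "permanent"), 0L)
})

test_that("urban residents can be excluded", {
  g <- generate_scenario(scenario_spec(groups = list(
    group_seasonal(10, "1", "3", 6, 7, name = "urban_mig"),
    group_seasonal(10, "2", "3", 6, 7, name = "rural_mig")),
    partition = synthetic_partition(12, 4, urban_zones = "1"), seed = 6))
  daily <- interpolate_missing(
    daily_preferential(build_trajectories(g$events), g$calendar, g$partition))
  mpl <- aggregate_space(aggregate_time(daily, "monthly"), g$partition)
  cfg <- selection_config("3", min_consecutive_months = 1, exclude_urban = TRUE)
  sel <- select_users(mpl, daily, g$partition, cfg)
  grp <- g$truth$users$group[match(sel$selected, g$truth$users$user_id)]
  expect_false(any(grp == "urban_mig"))
  expect_gt(sum(grp == "rural_mig"), 0L)
})

test_that("binarization produces the in-zone indicator and enforces its contract", {
  zones <- c("z1", "z2")
  mpl <- toy_mpl(list(
    c(1L, 1L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
    rep(1L, 12)), zones)
  B <- binarize(mpl, "u01", "z2")
  expect_equal(unname(B[1, ]), c(0L, 0L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(nrow(B), 1L)
  expect_error(binarize(mpl, c("u01", "u02"), "z2"), "contract")
  expect_error(binarize(mpl, character(0), "z2"), "no users")
})
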