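# cdrmob — multi-resolution mobility profiling from anonymized call records

`cdrmob` turns anonymized, region-quantized call detail records (CDRs) —
one row per call with a user id, a 10-minute-quantized timestamp and the
serving administrative region — into population-level descriptions of
seasonal human mobility. It was built for food-security and
epidemiological monitoring settings (the motivating geography is Senegal's
123 arrondissements grouped into 13 livelihood zones), where year-long CDR
exports are one of the few timely, country-wide views of how rural and
urban populations move with the agricultural calendar.

The package is aimed at quantitative epidemiologists, demographers and
food-security analysts who have (or simulate) event-level CDR exports and
want reproducible seasonal mobility indicators rather than ad-hoc scripts.

## The method

The central object is the **individual-trajectory matrix**: an `N × N_T`
integer matrix with one row per user and one column per time bin, whose
cells are region (or zone) labels. It is built in a fixed order:

1. **Regularization.** Each user's irregular event sequence
   `q_p = [Q(x_p(t_{p,1})), …, Q(x_p(t_{p,n_p}))]` is collapsed to a daily
   series by taking the *daily preferential region* — the most-visited
   region that day (ties go to the region visited earliest). Days with no
   activity are missing.
2. **Interpolation.** Missing days take the last known position; a missing
   run at the head of the year is backfilled with the first active day.
   After interpolation every user is somewhere every day, so column sums of
   the derived population counts equal `N` exactly.
3. **Aggregation.** Coarser time resolutions take the per-window mode of
   the daily series (365 → 53 weekly → 24 biweekly → 12 monthly columns for
   a non-leap year); coarser space maps regions onto zones.
4. **Counts and signatures.** `count(z, t)` = users whose preferential
   location at bin `t` is zone `z`; z-scored per zone (population standard
   deviation) these give comparable seasonal signatures.
5. **Selection.** Candidate seasonal migrants for a target zone are chosen
   by occupancy class (occasional = 1 month, moving = 2–11, permanent =
   12), a radius-of-gyration filter for "regular travelers" (maximum
   day-to-day centroid move ≤ ratio × r_g), optional urban exclusion, and
   four temporal constraints (minimum consecutive months in the target,
   maximum total months, minimum months elsewhere, required period).
6. **Profiles.** Selected users' monthly rows are binarized (1 = in the
   target zone) and clustered hierarchically under Jaccard distance
   `1 − |a∧b|/|a∨b|`; the dendrogram cut at `k` gives the zone's mobility
   profiles, each with a monthly count curve.
7. **Fusion.** Profile signatures are correlated (lagged Pearson) and
   aligned with external zone-level series such as rainfall or NDVI.

A seeded synthetic CDR generator (`scenario_spec()` / `generate_scenario()`)
plants permanent, occasional and seasonal-migrant behaviors with full
ground truth, so the whole pipeline is testable without access-restricted
operator data.

## Worked example

```r
library(cdrmob)

part <- synthetic_partition(n_regions = 123, n_zones = 13)
spec <- scenario_spec(
  groups = list(
    group_permanent(250, "10"),
    group_seasonal(100, "10", "1", depart_month = 6, return_month = 7,
                   name = "rainy_season_migrant"),
    group_seasonal(100, "10", "1", depart_month = 9, return_month = 10,
                   name = "harvest_migrant"),
    group_occasional(50, "2", "10", visit_month = 4)),
  partition = part, seed = 2013)
g <- generate_scenario(spec)

traj  <- build_trajectories(g$events)
daily <- interpolate_missing(daily_preferential(traj, g$calendar, g$partition))
daily
#> itmatrix: 500 users x 365 daily bins, region level (123 labels), interpolated

mpl <- aggregate_space(aggregate_time(daily, "monthly"), g$partition)
r <- occupancy_stats(mpl)$ratios
r[r$zone == "10", ]
#>    zone visitors occasional moving permanent
#> 10   10      500        0.1    0.4       0.5
```

The occupancy classes recover the planted mix exactly: 10% occasional
visitors, 40% moving (the two migrant groups), 50% permanent residents of
zone 10. Selection then drops non-movers and one-month visitors, and the
binarized profiles split into the two migrant schedules:

```r
sel <- select_users(mpl, daily, g$partition, selection_config("10"))
sel$audit
#>              stage removed remaining
#> 1   visited_target       0       500
#> 2        nonmoving     250       250
#> 3 regular_traveler       0       250
#> 4  min_consecutive      50       200
#> 5       max_months       0       200
#> 6    min_elsewhere       0       200

ps <- hierarchical_profiles(binarize(mpl, sel$selected, "10"), k = 2)
ps
#> mobility_profiles: k = 2 (average linkage), target zone 10; sizes: 100, 100
ps$curves[, 5:10]      # months May..October in the target zone
#>          [,1] [,2] [,3] [,4] [,5] [,6]
#> profile1  100    0  100  100  100  100
#> profile2  100  100  100  100    0  100

event_alignment_report(list("10" = ps), g$rainfall)
#>   zone profile onset_month change_month change_sign lag
#> 1   10       1           6            6          -1   0
#> 2   10       2           6            9          -1   3
```

Profile 1 leaves the zone in June — exactly at the synthetic rainfall
onset (lag 0) — while profile 2's departure trails it by three months:
the alignment report quantifies which mobility profile responds to the
rainy season.

The same workflow is scriptable from a shell via
`Rscript inst/cli/cdrmob.R simulate|run ...` (see the file header for
flags), driven by a YAML configuration.

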