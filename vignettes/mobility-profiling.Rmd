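---
title: "Seasonal mobility profiling from call detail records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal mobility profiling from call detail records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrmob)
```

# The problem and the data model

Call detail records observe a person's position only when they make a
call, at the serving antenna's location, quantized in space to an
administrative region and in time (here) to 10-minute ticks. The resulting
per-user event sequences have different lengths and sampling times, so
they cannot be compared or aggregated directly. `cdrmob` regularizes them
into a single rectangular object — the individual-trajectory matrix, an
`N × N_T` matrix of region labels with one row per user — and derives all
downstream quantities (population counts, seasonal signatures, occupancy
classes, mobility profiles) from that object.

Two modelling assumptions underlie everything that follows:

* **The daily preferential region is an adequate home-location proxy.**
  The most-visited region of a day stands in for where the user "is" that
  day. Hour-of-day refinements (evening calls weighted toward home) are
  known to sharpen this estimate for high-activity populations but are not
  implemented; daily majority is the estimator used throughout.
* **Phone silence means "stayed put".** Missing days are filled with the
  last known position (and a silent head of the year backwards from the
  first active day). This is the right bias for detecting *departures* —
  a user who moves and calls from the new zone is seen moving — but it
  undercounts short trips made without phone activity.

# Regularization and aggregation

`daily_preferential()` computes, per user and day, the region with the
most event records; a day with no events is the missing sentinel `0`.
Ties are broken toward the region visited **earliest within the day**.
The obvious alternative (breaking ties by label order) would make
results depend on how regions happen to be numbered; time-of-first-visit
is deterministic and meaningful. The same rule applies per window in
`aggregate_time()`.

Coarser matrices are always recomputed from the daily matrix, never from
intermediate resolutions, so a monthly cell is the mode over the month's
days rather than a mode of modes; this avoids compounding tie artifacts.
For a 365-day year the column counts are 365 (daily), 53 (weekly:
consecutive 7-day blocks anchored at January 1, the 53rd holding the final
day), 24 (biweekly: days 1–15 and 16–end of each month) and 12 (monthly).
Fourteen-day blocks would give 27 bins, not 24; two half-months per
calendar month is the only reading compatible with 24. Leap years (366
daily bins) are supported; all defaults use 2013.

The canonical operation order is **time first, then space**: the daily
region matrix is aggregated to the target resolution and only then mapped
through the region→zone table. Space-then-time can disagree (the zone mode
of a window need not be the zone of the region mode); the package exposes
both but fixes time-first as the pipeline order, and the test suite checks
the zone-level result against an explicit per-window zone-mode oracle.

Interpolation's contracts are tested directly: it is idempotent, never
alters an observed cell, and after it every column of the count matrix
sums to `N` exactly. `interpolation_bias()` quantifies what interpolation
added per zone as `100 · mean_t (interp − raw)/interp`, skipping bins with
a zero interpolated count; the denominator is switchable to the raw count.
The per-bin added-user series is returned so early-year concentration
(head backfill) can be inspected. `low_frequency_fraction()` supports the
coarsening step: it reports the share of spectral power (DC excluded) in
the lowest fraction of frequencies of a z-scored signature; seasonal
scenarios put >0.95 of the power there, which is what justifies monthly
analysis in the first place.

# Selection of candidate migrants

For a target zone, users are filtered in a fixed, audited order: visited
the zone; not permanent there (12/12 months); not a "regular traveler";
optionally not resident in an urban-flagged region; then the four temporal
constraints (longest consecutive run in the target ≥ minimum — runs do not
wrap December→January; total months ≤ maximum; months in some other single
zone ≥ minimum — the alternative "sum over all other zones" reading is
available via `elsewhere_mode = "sum"`; presence during a required set of
months). The audit reports removals per stage so the discarded share of
the population is always visible.

The **regular-traveler filter** removes users whose largest day-to-day
centroid move does not exceed `ratio × r_g` (default ratio 3), where the
radius of gyration `r_g` is the root-mean-square distance of the user's
daily positions from their visit-weighted mean, computed with equal day
weights on the interpolated daily row, in a local planar frame (km). Two
numerical caveats are worth knowing:

* The filter is sensitive to region geometry (moves are measured between
  centroids), and — less obviously — to migration *duration*: for a user
  splitting the year between two sites a fraction `f` apart, the single
  big move `D` satisfies `D ≤ 3 r_g = 3 D √(f(1−f))` whenever
  `f ∈ [0.13, 0.87]`. A user away for four months is therefore flagged
  "regular" by their own migration. Short (about one-month) migrations
  pass the default ratio; analyses targeting long migrations should lower
  the ratio threshold.
* A user with `r_g = 0` and no moves is regular; with any move and
  `r_g = 0`, non-regular — both follow from the comparison itself.

Urban residence is defined as the user's most-occupied daily region
carrying the urban flag; deriving the flags (e.g. from night-time lights)
is upstream of this package, which consumes them as a boolean column.

# Mobility profiles

Selected users' monthly zone rows are binarized to in-target indicators
and clustered agglomeratively under Jaccard distance, the natural
dissimilarity for presence patterns (shared absences carry no weight).
The distance matrix is computed by cross-products and is verified in tests
against both the pairwise definition and `stats::dist(method = "binary")`;
metric axioms are verified exhaustively over all binary vectors up to
length 6. The tree is cut at a user-chosen `k` (3–4 is typical; a
silhouette-vs-k report is provided but no automatic selection is done).
Cluster labels are assigned by decreasing size.

Linkage notes:

* `average` is the default; `complete` is offered and generally agrees on
  separated data; `ward` applies the Lance–Williams Ward update to the
  Jaccard matrix as-is, which is mathematically improper for a
  non-Euclidean distance — it is kept as a robustness check only.
* Agglomeration is delegated to `stats::hclust`. Tied merge heights —
  ubiquitous with binary data, where duplicate rows sit at distance 0 —
  are resolved by `hclust`'s input-order rule. No index-based tie-break
  can be permutation-invariant, so the package guarantees (and tests)
  stability at the level that matters: the cut partition of separated
  groups is identical under row permutation, even though the merge order
  inside a cluster is not.

# The synthetic scenario generator

`generate_scenario()` emulates the structure of a year-long operator
export: a fixed 2013 calendar, a partition of 123 regions grouped into 13
zones by default (zone 1 urban, standing in for the capital), user groups
with planted itineraries (permanent; occasional one-month visitors;
seasonal migrants away from `depart_month` to `return_month − 1`), and a
call model of a mean 4 calls per active day, a 0.2 daily inactivity
probability (≈292 active days/year) and a 256-day activity floor matching
the filter such datasets ship with. Within a month a user keeps one
uniformly drawn region of their zone, so day-to-day moves are mostly
within zone, as at administrative-region resolution in reality. All
sampling comes from one seeded stream in a fixed per-user order, so
emitted files are byte-identical across runs.

The synthetic rainfall series is a Gaussian bump per rural zone whose
half-peak crossing lands exactly on the configured onset month (default
June, peak August), so onset detection in `event_alignment_report()`
(first month ≥ 0.5 × the zone's peak; the 0.5 is a declared convention)
has an unambiguous planted truth.

For clustering experiments, `generate_binary_profiles()` plants noisy
copies of group templates with an independent per-cell flip probability
(default 0.05). The canonical templates
(`seasonal_profile_templates()`) are three six-month occupancy windows
overlapping by two months on a ring. The overlap is deliberate: with
fully disjoint supports most between-group Jaccard distances equal 1
exactly, agglomeration heights saturate, and the `k = 3` cut degenerates
into tie-order artifacts under complete linkage. Keeping pairwise
template distances at 5/6 — large but unsaturated — makes recovery a
property of the data rather than of tie handling. A flipped row that
degenerates to all zeros (undefined Jaccard distance) has its noise
redrawn.

What the generator does **not** emulate: antenna-level spatial noise,
social call structure, overseas visitors, multi-day trips without calls,
and activity that correlates with movement. Passing tests on synthetic
scenarios therefore demonstrate the pipeline's correctness and its
behavior under controlled missingness — not that real CDR populations
satisfy the home-proxy or silence-means-staying assumptions.

# Numerical choices and degenerate inputs

* Missing sentinel is `0`; labels are 1-based within one integer matrix.
* Z-scores use the population standard deviation (divide by `n`), so a
  z-scored series satisfies `Σz = 0`, `Σz² = n` exactly; constant series
  map to all zeros rather than NaN.
* Lagged correlation at lag `L` pairs `a[t]` with `b[t+L]` over the
  overlap, no wrap-around; it is flagged undefined below 3 overlapping
  bins or for a constant window. No multiple-testing correction is
  applied — the fusion outputs are descriptive.
* Distances: great-circle (haversine) between centroids for move lengths;
  a local planar approximation around the weighted mean for `r_g` (exact
  to well under 1% at intra-country scales).
* All-missing trajectory rows are an error at interpolation time — users
  below the activity floor should be excluded during ingest, not silently
  invented.
* Gap-length capping for interpolation is available but off by default:
  last-known-position across arbitrarily long gaps is the documented rule.

# Problem sizes

The test suite and the acceptance script run scenarios of 30–2,000 users
over a full 365-day year (up to ≈2.3 million events), 123 regions and 13
zones, with clustering on 300 planted profiles; these sizes exercise every
code path at full-year scale while keeping a complete run in the order of
minutes on one CPU. The pipeline itself is linear in events and users and
has been structured (data.table grouping, vectorized per-bin modes) so
that national-scale exports are limited by memory, not algorithmics;
distributed execution is explicitly out of scope.

# Known limitations

* The home-location estimate ignores hour-of-day structure.
* The regular-traveler filter's duration sensitivity (above) means
  "unusual movement" is only meaningfully defined relative to the chosen
  ratio threshold.
* Occupancy classes are calendar-bound: a migration spanning New Year
  splits across two study years.
* External series are consumed pre-aggregated per zone; raster processing
  and polygon-overlap zone assignment are upstream concerns.
* One year of data cannot separate seasonal behavior from secular change;
  multi-year baselines are future work.
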