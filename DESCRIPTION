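Package: cdrmob
Title: Multi-Resolution Mobility Profiling from Anonymized Call Detail Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts anonymized, region-quantized call detail records (CDRs)
    into regularized individual-trajectory matrices at daily, weekly,
    biweekly and monthly resolution, derives dynamic population counts and
    z-scored seasonal signatures per geographic zone, selects candidate
    seasonal migrants through occupancy, radius-of-gyration and temporal
    constraints, clusters binarized monthly occupancy profiles with Jaccard
    distance and hierarchical linkage into mobility profiles, and aligns the
    resulting seasonal curves with external environmental series such as
    rainfall and vegetation indices. Includes a seeded synthetic CDR
    generator with planted ground-truth mobility behaviors so the full
    pipeline is testable without access-restricted operator data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    geosphere,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
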