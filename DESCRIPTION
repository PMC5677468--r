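Package: cachescape
Title: Stage-Conditional Odds and Spatial Clustering of Seed-Cache Fates
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of early tree recruitment from bird-dispersed seed
    caches monitored over two years. Provides a validated cache-fate table
    format, stage-conditional cohorts (pilferage, first-year germination,
    seedling survival, two-year germination), pairwise odds-ratio contrasts
    between study areas, elevation zones and microsite types with
    configurable confidence intervals, Ripley's K estimation with edge
    correction, the success-minus-failure difference of K functions with
    pointwise random-labeling permutation envelopes, and a synthetic
    cachescape generator that emulates a stratified two-area caching
    experiment so that every stage of the pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
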