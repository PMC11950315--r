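Package: heatscape
Title: Urban Heatwave Indices, Model Ranking, and Composite Heat-Risk Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for projecting urban heatwave hazard from daily
    near-surface temperature series. Detects heatwave events as runs of three or
    more consecutive days strictly above a city's fixed baseline 95th-percentile
    threshold, computes five annual indices (heatwave number, total days, longest
    duration, mean temperature, hottest temperature) for daytime (tasmax) and
    nighttime (tasmin) records, ranks climate models against a reference dataset
    with a rank-points scheme and half-maximum selection threshold, quantifies
    percentage changes relative to each model's own baseline with regional
    multi-model median and interquartile spread, aggregates the indices into a
    min-max normalized composite heatwave index (CHI), overlays CHI with
    population scenarios to produce absolute and change-based heat-risk indices,
    and classifies cities as coastal or inland by great-circle distance to a
    coastline. Includes a seedable synthetic generator for multi-city,
    multi-model daily temperature ensembles and SSP-style population
    trajectories so the full pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
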