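Package: carbonledger
Title: Consolidated Global Carbon Budget Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mass-balance accounting of the global carbon budget:
    the budget-imbalance identity over the five annual flux components
    (fossil and land-use-change emissions, land and ocean sinks, atmospheric
    growth), flux-level bias corrections (transient carbon densities for
    bookkeeping land-use emissions, replaced sinks and sources and lateral
    carbon export for the land sink, model scaling and cool-skin adjustment
    for the ocean sink), an inversion-ensemble estimator of the ppm-to-GtC
    conversion factor with uncertainty propagation, attribution of sink
    weakening to climate change, and a synthetic-ensemble generator with
    exact mass balance for end-to-end validation. Functions take and return
    tibbles so pipelines compose with the pipe; fitted objects provide
    tidy() and glance() methods and results plot with autoplot().
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
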