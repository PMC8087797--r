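Package: fluvialfire
Title: Wildfire Impacts on Stream and River Networks
Version: 0.1.0
Authors@R: person("Analysis", "Team", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end pipeline quantifying wildfire impacts on fluvial
    networks. Generates synthetic Horton-law stream networks, burn scars
    with severity patches, ecoregion partitions, and multi-station
    dissolved-oxygen sonde series; computes stream + river length burned
    within fire perimeters (SL_BA) with severity and minimum-area
    filtering; estimates temporal trends (Theil-Sen with Mann-Kendall
    significance) and binned regressions; detects dissolved-oxygen sags,
    fits a two-component exponential longitudinal decay, and solves for
    the downstream extent of water-quality disturbance (SL_LE), validated
    against a Horton's-law geometric-series stream-order model; combines
    SL_BA and SL_LE into per-ecoregion percent-of-network summaries with
    bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
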