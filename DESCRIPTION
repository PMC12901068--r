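Package: coflux
Title: Edge Time Series Co-Fluctuation Dynamics for Parcellated BOLD Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying brain network dynamics through edge functional
    connectivity. From parcellated nodal BOLD time series the package builds
    z-scored node signals, edge time series (per-timepoint products of node
    pairs), the edge functional connectivity (eFC) matrix, and the root sum
    square (RSS) co-fluctuation amplitude trace, for the whole brain or for a
    node subset such as the default mode network. Troughs and peaks of the RSS
    trace are extracted under a family of percent-magnitude criteria,
    summarized per subject as trough-to-trough durations and peak heights, and
    compared between groups with a general linear model adjusting for age and
    total brain volume (covariate-adjusted marginal means with standard
    errors). A synthetic cohort generator with hidden covariance-regime
    switching provides fully reproducible two-group test beds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, data.table, jsonlite
Suggests: testthat (>= 3.0.0), emmeans, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
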