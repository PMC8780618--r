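Package: cohortdemog
Title: Instar Determination and Cohort Life-Table Demography for Insect
    Life-History Studies
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two classic life-history analyses of laboratory-reared
    insect cohorts. First, larval instar determination from head-capsule
    morphometrics: kernel density estimation with mode counting, the excess
    mass test of multimodality with smoothed-bootstrap calibration, antimode
    cut-points, Brooks-Dyar growth ratios and the log-linear growth
    regression. Second, cohort life-table demography: lx/mx schedules built
    from individual rearing records and the derived population parameters
    (net reproductive rate, generation time, intrinsic rate of increase,
    doubling time, finite rate of increase) with jackknife or bootstrap
    confidence intervals. A synthetic-data module generates head-capsule
    samples and individual-based cohorts with known ground truth, including
    exact expected-schedule oracles, so every analysis stage is testable
    without access to any particular rearing data set.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
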