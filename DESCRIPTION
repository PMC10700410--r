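Package: pdrive
Title: Proportional-Derivative Control Modelling of a Stop-Sign Driving Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a rapid motor-control task in which a
    participant drives a virtual car to a stop sign and holds it there.
    Car acceleration is modelled with proportional-derivative (PD)
    feedback control; per-trial drive (K_p) and damping (K_d) gains are
    estimated by zero-intercept least squares on frame-sampled
    trajectories and model fit is quantified by forward simulation.
    Includes a seeded synthetic-cohort generator with known ground truth,
    split-half and test-retest reliability statistics (Pearson split-half
    correlations, Fisher z comparison of correlations, ICC(3,1)),
    standardized-coefficient covariate regressions, and an end-to-end
    pipeline with CSV interfaces and averaged velocity-trace reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
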