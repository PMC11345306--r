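Package: gaitvar
Title: Longitudinal Gait-Instability Analysis for Growing Dogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Serial analysis of inertial-measurement-unit (IMU) derived gait
    features in growing dogs at risk of hip dysplasia (HD). Implements
    plausibility filtering with whole-day exclusions, per-day averaging of
    replicate walking trials, a minimum-measurement-days cohort filter,
    per-dog linear detrending of each gait feature against age with a
    mean-square-error (MSE) instability score, pathological-side alignment
    with mirroring of symmetry features, and healthy-versus-HD group
    comparison via Shapiro-Wilk checks and pooled two-sample t-tests.
    Includes a synthetic-cohort simulator reproducing the longitudinal
    study design (monthly then bimonthly visits, up to three runs per day,
    group-dependent dispersion) so that every pipeline stage is testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    readr,
    tibble,
    rlang,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
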