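Package: wristpa
Title: Processing of Raw Wrist-Worn Accelerometer Data into Physical
    Activity Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts raw 100 Hz triaxial wrist acceleration recordings into
    calibrated, wear-time-corrected physical activity summaries. Implements
    gravity autocalibration by iterated unit-sphere least squares on
    stationary windows, resampling with interrupt handling, low-pass machine
    noise removal, Euclidean-norm-minus-one (ENMO) activity metrics, five
    second epoch aggregation, stationary-episode non-wear detection with
    time-of-day imputation, intensity distributions, participant and cohort
    descriptive summaries, a minimum-wear-time reliability (ICC) simulation,
    and a synthetic raw-data generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
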