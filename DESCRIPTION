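Package: painwear
Title: Estimating Subjective Pain Scores from Wearable Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for between-subject estimation of subjective 0-10 pain
    scores from multichannel wearable sensor data recorded during treatment of
    acute sickle-cell pain. Sparse, minute-resolution pain reports (patient app
    or nurse chart) are matched to one-minute sensor segments, denoised with a
    moving-average filter, summarised by eight per-channel statistics, reduced
    by greedy wrapper feature selection under cross-validation, and modelled
    with ridge, lasso, Gaussian-process and support-vector regression plus a
    four-level support-vector classifier. Includes a seeded synthetic-cohort
    generator that emulates the statistical structure of such studies so every
    stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    kernlab
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
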