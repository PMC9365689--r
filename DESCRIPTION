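Package: ingestphase
Title: Stage-Resolved Analysis of Neural Responses to Ingestion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and quantifying oral, gastrointestinal and
    systemic (post-absorptive) neural responses to fluid and nutrient
    ingestion in single-cell calcium-imaging traces and fibre-photometry
    signals. Provides baseline z-score normalization, isosbestic dF/F0
    correction, bleaching-artifact screening, epoch-based response
    classification with population-weighted z-scores, sigmoidal onset-latency
    (t50) and persistence estimation, lick-bout and fluid-preference
    behavioural metrics, accelerometer-based movement segmentation,
    permutation tests and intra-class correlation, and a seeded synthetic
    session generator with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
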