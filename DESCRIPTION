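Package: cgmtempo
Title: Temporal Risk Profiling of Hypoglycemia from Continuous Glucose Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the timing of hypoglycemia in continuous glucose
    monitoring (CGM) traces. Reads Dexcom-CLARITY-style and normalized CSV exports,
    segments traces into maximal below-threshold hypoglycemia episodes at 5-minute
    epochs, bins monitored and hypoglycemic minutes by hour of day, summarises
    arbitrary clock-time windows (including windows crossing midnight), sweeps
    hypoglycemia thresholds, and runs the minute-count contingency and rank tests
    used for subgroup comparisons. Includes a seeded semi-Markov synthetic CGM
    cohort generator with known ground truth for end-to-end pipeline validation
    and parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
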