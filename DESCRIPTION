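Package: iatdscore
Title: Scoring of Implicit Association Test Data with the D-Score Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-level scoring of Implicit Association Test (IAT) data with
    the six classical D-score algorithms (D1-D6), which combine built-in or
    ex-post error-latency inflation with an optional lower-tail (< 400 ms)
    deletion. Implements the standard trial- and participant-level cleaning
    rules (latency > 10,000 ms removal, fast-participant and accuracy-based
    exclusion), per-block and per-condition descriptive statistics,
    practice-test reliability, effect-size banding, plot-data construction,
    and a seeded ex-Gaussian synthetic IAT data generator so the whole
    pipeline can be exercised without real participant data. A command-line
    entry point covers batch scoring, simulation and plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ggplot2,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
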