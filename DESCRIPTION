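Package: quitsens
Title: Two-Stage Imputation Sensitivity Analysis for Tobacco Abstinence
    Outcomes with Missing Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sensitivity analysis for smoking-cessation trials whose primary
    outcome is biochemically verified abstinence and whose data are missing at
    two stages: the self-report survey and the urine (cotinine) verification.
    Implements odds-ratio-indexed single imputation on aggregated per-arm
    counts, spanning missing-at-random (OR = 1) through the conventional
    "missing = smoking" rule (OR = infinity), with sensitivity factors for
    urine availability (lambda) and would-be verification results (eta) among
    survey non-respondents. Includes pooled contrast estimation (rates, odds
    ratios, Pearson chi-square tests on possibly fractional counts), full
    sensitivity grids, a packaged fixture of a 2x2 factorial quit-and-win
    trial, an individual-level trial simulator with missing-not-at-random
    mechanisms for parameter-recovery experiments, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    optparse,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
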