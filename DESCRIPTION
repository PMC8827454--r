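Package: twaki
Title: Triple Whammy Nephrotoxicity Signal Detection and Time-to-Onset
    Analysis for Spontaneous Report Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for studying acute kidney injury (AKI)
    associated with "Triple Whammy" combination therapy (renin-angiotensin
    system inhibitors, diuretics, and NSAIDs) in JADER-style spontaneous
    adverse drug event report databases. Reads and joins DEMO/DRUG/REAC
    report tables, applies population and exposure filters, flags AKI cases
    from a configurable MedDRA Preferred Term list, classifies drug
    combination patterns, computes crude and covariate-adjusted reporting
    odds ratios with signal flags, and analyses time from the last-started
    combination drug to AKI onset via two-parameter Weibull shape tests,
    Kaplan-Meier cumulative incidence, and the Gehan generalized Wilcoxon
    test. Includes a fully parameterised synthetic report-database
    generator with known ground truth so every stage of the pipeline can
    be validated without access to the live database.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    fitdistrplus,
    optparse,
    readxl,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
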