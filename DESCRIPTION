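Package: glycostrat
Title: Glycemic Metrics and Stratification for Intermittently Scanned CGM Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes consensus continuous-glucose-monitoring metrics (time in,
    above and below range, coefficient of variation, glucose management
    indicator, scan frequency, sensor usage) from intermittently scanned
    sensor exports, classifies patients against the ATTD-2019 pediatric
    targets, a four-colour triage algorithm and the Glycemic Risk Index,
    stratifies cohorts by age band and centre size, runs the associated
    descriptive and comparative statistics with Benjamini-Hochberg
    correction, and renders cohort reports. Includes a lognormal AR(1)
    trace simulator so whole cohorts can be generated, calibrated to
    published band-level range profiles, and analysed end to end without
    any patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
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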