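Package: pipscreen
Title: Screening Dispensing Claims for Potentially Inappropriate Prescribing
Version: 0.1.0
Authors@R: person("Open", "Contributor", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A rule engine and analysis pipeline for measuring potentially
    inappropriate prescribing (PIP) in longitudinal prescription-dispensing
    records using explicit, criterion-based prescribing standards for
    middle-aged adults (45-64 years). Builds drug-exposure episodes and
    calendar-month class occupancy from dispensing events coded in either ATC
    or BNF systems, evaluates declarative criteria of five structural
    categories (duration, dose plus duration, co-prescription, first-line,
    same-month duplication), computes polypharmacy (four or more drug classes
    each dispensed at least three times in the study year), estimates
    prevalence with Wald confidence intervals, and fits unadjusted and
    adjusted logistic regressions for PIP determinants. Ships a synthetic
    dispensing-data generator with plantable criterion-positive and
    criterion-negative patterns so the whole pipeline is testable without
    access to real claims databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
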