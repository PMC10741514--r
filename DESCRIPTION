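Package: prrsignal
Title: Disproportionality Analysis of Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on spontaneous
    adverse drug reaction report databases in the style of the FDA Adverse
    Event Reporting System (FAERS). Provides a validated report-level data
    model with CSV and JSON-lines input/output, per-drug case counting for
    an index MedDRA preferred term, a minimum-report inclusion filter, 2x2
    contingency construction, the proportional reporting ratio (PRR) with a
    log-normal Wald confidence interval, tiered signal classification, a
    concomitant-medication "unmasking" re-analysis, descriptive breakdowns
    (reporter type, reason for use, country, year, mean age), and a seeded
    synthetic-report generator with a closed-form expected PRR for end-to-end
    testing without access to a live database.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
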