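Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Report Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance signal-detection pipeline for
    spontaneous adverse-event report databases in the FDA Adverse Event
    Reporting System (FAERS) quarterly ASCII dialect. Parses the multi-table
    case structure (DEMO, DRUG, REAC, THER, OUTC, RPSR), removes duplicate
    case versions, normalizes drug names, filters to primary-suspect reports
    for a target drug, maps MedDRA preferred terms to system organ classes,
    and builds 2x2 contingency tables for every drug-event pair. Computes
    four disproportionality statistics - reporting odds ratio (ROR),
    proportional reporting ratio (PRR) with Yates-corrected chi-square, the
    BCPNN information component (IC, IC025), and the multi-item gamma-Poisson
    shrinker (EBGM, EBGM05) with marginal maximum-likelihood prior fitting -
    and applies joint signal criteria. Also provides demographic and yearly
    report summaries, time-to-onset binning, gender-stratified volcano tables
    with false-discovery-rate control, and a synthetic report-database
    generator with planted relative-risk elevations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
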