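Package: lungsim
Title: Population-Level Lung Cancer Screening Microsimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo microsimulation of low-dose CT lung cancer screening
    for a multi-birth-cohort population with declining smoking prevalence.
    Generates synthetic smoking histories by birth cohort, simulates a
    parameterized lung cancer natural history (onset, histology, preclinical
    stage progression, detection, and cure-mixture survival), applies CMS
    screening eligibility with partial adherence, and compares screening
    against no screening under common random numbers. Computes mortality
    reduction, deaths avoided, life-years gained, overdiagnosis by two
    definitions, and adherence sensitivity, with across-replication means and
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
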