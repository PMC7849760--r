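Package: pddiscreen
Title: Screening Pharmacy Claims for Potential Drug-Drug Interactions of Analgesics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based screening pipeline for potential drug-drug
    interactions (pDDIs) of analgesic drugs in pharmacy dispensation claims.
    Detects same-calendar-month co-dispensation of drug pairs standing in
    possible conflict (NSAIDs with antihypertensives, other NSAIDs,
    glucocorticoids, oral anticoagulants, SSRIs/SNRIs and antiplatelet drugs;
    opioids with gabapentinoids and benzodiazepines; high-dose tramadol with
    SSRIs/SNRIs), attributes each flagged patient-month to one or multiple
    prescribers, and aggregates flags into cases, persistence histograms,
    population prevalence, and same-prescriber (co-prescribing) statistics.
    Includes a seeded synthetic claims generator with ground truth, and a
    deterministic fixture that expands published national aggregate tables
    into claim-level records for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
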