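Package: vigiprof
Title: Sex-Stratified Pharmacovigilance Signal Profiles for Benzodiazepine-Site Ligands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Disproportionality analysis of spontaneous adverse-event report
    tables, stratified by sex: 2x2 contingency tables per drug-event pair
    with the information component (IC) and its 95% credibility lower bound
    (IC025), proportional reporting ratio (PRR) and reporting odds ratio
    (ROR); signal screening (PRR > 2, IC025 > 0, at least five records);
    aggregation of screened signals up the MedDRA hierarchy as cumulative
    (cIC025) and summed cumulative (ScIC025) values with drug and report
    percentages; sex-contrast classification of paired female/male signals
    with a 2:1 IC025 ratio filter; and a chemical-similarity companion
    (shape-distance matrices from conformer similarity reports, descriptor
    PCA and hierarchical clustering). Includes a synthetic report generator
    with known baseline independence and injected drug-by-event-by-sex
    signals so the whole pipeline is testable without access to a curated
    FAERS extract.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    readr,
    tibble,
    rlang,
    jsonlite,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
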