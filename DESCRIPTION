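Package: pedtrends
Title: Inbreeding, Kinship and Effective Population Size Trends from
    Studbook Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Population analysis of closed studbook (registry) pedigrees:
    exact per-animal inbreeding coefficients by the Meuwissen-Luo tabular
    algorithm, pairwise kinship and cohort mean-kinship ("expected
    inbreeding") via indirect relationship-vector products, annual and
    per-generation rates of inbreeding by regression of ln(1-F) on birth
    year, effective population size, generation intervals, sire-usage
    concentration statistics, 5-year-block trend summaries, and a
    synthetic closed-population pedigree simulator with popular-sire
    skew, migration and census trends for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
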