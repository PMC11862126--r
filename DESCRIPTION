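Package: tppforms
Title: Functional Proteoform Group Analysis for Thermal Proteome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers functional proteoform groups from peptide-level thermal
    proteome profiling (TPP) melt curves and tests them for drug-induced
    melting shifts and cohort-scale abundance effects. Peptide reporter-ion
    tables are variance-stabilized, converted to relative melt profiles, and
    clustered per gene by Leiden community detection on weighted-Euclidean
    similarity graphs with modularity, ambiguity-ratio and community-size
    acceptance gates. Proteoform groups are screened for differential melting
    with NPARC F-tests using data-estimated effective degrees of freedom,
    summarized with four-parameter logistic fits, and carried into
    proteoform-aware over-representation analysis, flanking-motif proportion
    tests, and clinical-cohort statistics against randomized-membership null
    groupings. A synthetic-data module generates TPP experiments and patient
    cohorts with known ground truth so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    minpack.lm,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
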