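Package: pdacig
Title: Integrative Genomic Analysis of Resected Pancreatic Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative analysis pipeline for targeted-panel genomics of
    pancreatic ductal adenocarcinoma (PDAC) trial cohorts. Provides typed
    readers for clinical, variant, copy-number and expression tables; cancer
    cell fraction (CCF) inference with clonal/subclonal classification and
    Bradley-Terry modelling of mutation acquisition order; pairwise
    co-occurrence and mutual-exclusivity testing with false discovery rate
    control; non-negative matrix factorization of binary alteration profiles
    with subsampling stability analysis and Ward clustering of patients;
    housekeeping-normalized differential expression with biomarker group
    definition; Cox proportional-hazards models including treatment-by-
    biomarker interaction tests and a random-split resampling validation of
    subgroup treatment effects. A seed-deterministic synthetic cohort
    generator with stored ground truth supports end-to-end testing of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
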