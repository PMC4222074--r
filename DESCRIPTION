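Package: cnadrivers
Title: Copy-Number-Driven Driver Gene Discovery in Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated multi-omics analysis pipeline for discovering
    candidate driver genes from paired tumor/normal copy-number and
    expression profiles. Implements per-subject circular binary
    segmentation of aCGH log2-ratio profiles with noise-adaptive and
    fixed-threshold aberration calling, cohort-level recurrent-region
    detection, histology-differential ANOVA with cluster merging, a
    three-step driver-gene search (expression filters, correlation
    modules, sparse canonical correlation refinement), rank-based AUC
    validation with Monte-Carlo nulls, an L1-penalized histology
    classifier, and network enrichment analysis of driver target sets
    against pathway gene sets with degree-preserving permutation nulls.
    Ships a seeded synthetic-cohort generator with planted ground truth
    for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
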