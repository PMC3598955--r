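Package: hdmm
Title: Expression-Based Classification of Hyperdiploid Multiple Myeloma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies multiple myeloma samples into hyperdiploid (HMM) and
    non-hyperdiploid (NHMM) subtypes from gene expression profiles. Expression
    dosage effects of the eight recurrent trisomy chromosomes (3, 5, 7, 9, 11,
    15, 19 and 21) are summarized into a two-dimensional embedding (trisomy-
    chromosome mean, non-trisomy-chromosome mean) of per-sample standardized
    expression, and samples are classified by an ensemble of leave-one-out
    k-nearest-neighbor models with majority-vote confidence scores. Includes
    per-dataset centroid adjustment for cross-platform transfer, a weighted-KNN
    variant for unbalanced cohorts, copy-number-based truth calling from the
    trisomy/non-trisomy median ratio, and a synthetic cohort simulator so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
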