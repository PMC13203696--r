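Package: misselect
Title: Missingness Fingerprints and Pipeline Recommendation for Incomplete Clinical Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A meta-learning toolkit for choosing which prediction pipeline to
    deploy on an incomplete tabular clinical dataset.  Characterizes datasets
    by a ten-dimensional missingness fingerprint plus Little's MCAR test,
    expands a small dataset library by controlled quality perturbations
    (MCAR and MNAR missingness injection, label trimming), runs a pluggable
    pipeline portfolio over degradation grids, learns fingerprint feature
    weights by differential evolution against sweep-derived performance
    distances, and recommends pipelines for new datasets by weighted
    k-nearest-neighbour lookup with out-of-distribution safeguards.  Includes
    a leakage-safe leave-one-dataset-out evaluation harness (regret, win
    rate, oracle-gap decomposition, block bootstrap) and synthetic-data
    generators for every input, so the whole stack is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
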