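Package: katzmda
Title: KATZ-Based Prediction of Metabolite-Disease Associations on a
    Heterogeneous Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate metabolite-disease associations by KATZ
    path counting on a heterogeneous network that combines a bipartite
    association matrix, disease semantic similarity computed from MeSH-style
    disease DAGs, and Gaussian Interaction Profile (GIP) kernel similarities
    (with a logistic-transformed disease kernel). Includes truncated-series
    and closed-form KATZ scoring, leave-one-out and repeated k-fold
    cross-validation with rank-based ROC/AUC, random-walk-with-restart and
    personalized PageRank baselines, and a seeded synthetic-data generator
    with planted cluster structure for download-free benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
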