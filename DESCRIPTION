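Package: toxlinker
Title: Evidence Aggregation for Investigative Toxicology Hypothesis Generation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Aggregates direct and inferred evidence linking a drug candidate,
    its structural analogs and its known or predicted secondary targets to an
    adverse preclinical finding. Combines Tanimoto fingerprint similarity
    search over chemical libraries, a chemical-gene-disease knowledge graph in
    the Comparative Toxicogenomics Database flat-file dialect with a
    hypergeometric shared-partner enrichment statistic, per-target Bernoulli
    naive Bayes activity classifiers, assay-potency profiling and a gene-level
    toxicity evidence scoreboard, and renders the result as a six-section
    hypothesis report. Includes a deterministic synthetic-fixture generator so
    the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
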