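Package: gochrono
Title: Time-Indexed Gene Ontology Annotation Histories and Enrichment Stability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A time-indexed store of Gene Ontology editions and gene
    annotation (GOA) editions, with the historical statistics needed to
    study how annotations change: per-gene and per-term count series,
    semantic-similarity (Jaccard) series, multifunctionality scores and
    taxon-wide annotation trends. Provides time-point-anchored
    overrepresentation analysis (hypergeometric test with
    Benjamini-Hochberg FDR control) and a framework for measuring the
    stability of enrichment results between a publication-era edition and
    a current edition, calibrated against a permutation null of re-paired
    hit lists. Includes a synthetic-history generator (growing ontology
    DAG, annotation churn, redundancy-purge discontinuities,
    preferential-attachment inequality, drifting hit-list modules) so
    every component is testable offline, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
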