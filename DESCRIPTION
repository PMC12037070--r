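Package: rrnclust
Title: Quantitative Pipelines for Bacterial rRNA Operon Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the three quantitative assays used to study spatial
    clustering of ribosomal RNA (rrn) operons on the Escherichia coli
    chromosome: two-channel fluorescent-focus pair-distance analysis
    (detection, nearest-neighbour pairing, nm scaling, median/fold-change
    comparison), Mu-transposition genome contact mapping (100-bin genome
    partition, read-depth and replication-bias normalization, replicate
    aggregation, per-bin tests), and dCas9 pulldown spectral-count
    enrichment against a lacZ control (robust z-scores, permutation FDR,
    cross-sample intersections). Includes closed-form reporter
    quantification (Miller units, CFU survival) and synthetic-data
    generators with ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    stats,
    tools,
    utils,
    generics,
    withr,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
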