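Package: oadsim
Title: Ontology-Aware Disease Similarity and Multi-Layer Disease
    Association Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building disease association networks for autoimmune
    and autoinflammatory diseases from multi-modal annotation data and
    hierarchical biomedical ontologies. Implements Wang-method semantic
    similarity on OBO ontology DAGs, best-match-average (FunSimAvg)
    ontology-aware disease similarity with weighted (differential
    co-expression), cell-proportion and drug-based variants, permutation
    significance, percentile-thresholded network construction with topology
    and power-law diagnostics, within-network distance (WiND) statistics,
    Ward/Leiden community detection with robust-community consensus and
    Fisher enrichment, similarity network fusion, and minimum-spanning-tree
    disease trajectories. A seeded synthetic-data generator with planted
    community structure exercises the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
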