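Package: netpharm
Title: Network Pharmacology Screening for Herb-Compound-Target-Disease Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds compound-target, herb-target-disease and seeded
    protein-protein interaction networks from scored interaction tables,
    screens nodes by degree, betweenness and closeness centrality
    (one- and two-stage), and performs local hypergeometric
    over-representation analysis with fold enrichment and
    Benjamini-Hochberg adjustment over GMT gene sets. Includes a
    deterministic synthetic-data generator (preferential-attachment PPI
    layer, planted hubs and planted enriched term) so the whole pipeline
    is testable without database exports, plus Cytoscape-consumable
    network export (SIF, GraphML, TSV) and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
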