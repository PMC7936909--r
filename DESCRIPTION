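Package: netpharm
Title: Network Pharmacology Pipelines for Multi-Herb Formulas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of the network-pharmacology workflow
    used to dissect multi-component herbal formulas: ADME screening of
    compound libraries by oral bioavailability and drug-likeness, assembly of
    compound-target sets from known and predicted interactions, intersection
    with disease gene sets, bipartite component-target network topology with
    a dual-threshold (degree and betweenness centrality) key-node screen,
    confidence filtering of protein-protein interaction networks,
    hypergeometric/Fisher over-representation statistics with
    Benjamini-Hochberg correction, a count-based exact differential-expression
    stage with cross-species ortholog mapping and target verification, and
    construction of four-layer Herb-Compound-Target-Pathway networks. Ships a
    seeded synthetic-data generator so every stage is testable without
    database access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
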