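Package: mineppi
Title: Protein Complex Detection from Multi-Relationship Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Constructs a weighted multi-relationship protein interaction
    network by combining physical protein-protein interaction (PPI) topology,
    weighted by the edge clustering coefficient, with Gene Ontology annotation
    overlap in the biological process, molecular function and cellular
    component aspects. The network is decomposed into four single-relation
    weighted networks from which protein complexes are detected as
    high-cohesion, low-coupling subgraphs via greedy seed expansion under a
    weighted-density threshold, coupling-based pruning and overlap-based
    redundancy filtering. Includes benchmark matching (precision, recall,
    F-measure), hypergeometric functional-enrichment scoring, and a synthetic
    planted-complex data generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
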