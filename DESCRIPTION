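Package: mirfuse
Title: MiRNA Similarity Network Fusion and Set Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds miRNA functional similarity networks from three
    heterogeneous evidence sources (disease-association semantic
    similarity on a MeSH-like ontology, Gene Ontology annotation
    similarity of target genes, and shortest-path proximity of target
    genes on a protein-protein interaction network), fuses them by
    per-pair averaging, expands a user miRNA list by random walk with
    restart on the thresholded fused network, and tests the expanded
    list for over-representation against a GMT miRNA-set knowledge
    base with Benjamini-Hochberg false discovery control. Includes
    seeded synthetic-data generators for every input format so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
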