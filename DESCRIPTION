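Package: ppigo
Title: Expression-Weighted Protein Interaction Network Enrichment of GO Terms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects Gene Ontology terms whose annotated proteins are both
    differentially expressed between two conditions and topologically
    clustered in a protein-protein interaction (PPI) network. Edges of the
    PPI network are weighted by the fold-change of their endpoint proteins so
    that dysregulated interacting proteins become close; the clustering of a
    protein set is summarized by its total pairwise shortest-path distance
    (TPD). Significance is assessed against per-set-size Monte-Carlo null
    models with a normal approximation, and confidence is controlled by an
    empirical false discovery rate obtained by shuffling term-protein
    associations while preserving both bipartite marginals. Includes parsers
    for BioGRID and STRING interaction files, GMT/TSV annotation readers, a
    synthetic-data generator with planted dysregulated modules, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
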