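Package: obokit
Title: Indexing, Semantic Similarity and Visualization for Arbitrary
    Biomedical Ontologies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reads arbitrary biomedical ontologies from OBO 1.2 flat files
    into an indexed representation with precomputed ancestor and descendant
    closures, and provides structure-aware term-set operations (minimal
    sets, descendant exclusion and pruning), corpus-frequency information
    content, Resnik and Lin semantic similarity between terms, annotated
    objects and groups of objects with permutation-based significance, and
    export of pruned ontology subgraphs to Graphviz DOT.  Includes seeded
    generators for random ontologies and annotation corpora, and a
    command-line interface over the same operations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite
Config/testthat/edition: 3
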