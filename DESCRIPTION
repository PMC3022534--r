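Package: synexpr
Title: Synexpression Clustering and Enrichment of Ontology-Annotated Expression Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for curated in situ hybridization expression
    annotations placed on an anatomy ontology. Propagates ordinal expression
    strengths up the ontology by the maximal-propagation rule, classifies
    genes as regional, ubiquitous or not detected, clusters regional genes
    into synexpression groups with centered Pearson correlation and average
    linkage, summarises clusters by expression occupancy, and tests clusters
    for functional-term enrichment with the hypergeometric distribution,
    calibrating threshold-level significance by permutation of whole
    per-gene annotation bundles. Ships a synthetic-data generator that
    plants known synexpression modules and enriched functional terms so
    every stage can be benchmarked against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
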