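Package: funComplexDetect
Title: Protein Complex Detection from PPI Networks via Functional Grouping and Markov Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects protein complexes of all sizes from protein-protein
    interaction (PPI) networks under one framework. Proteins are first
    grouped by their hierarchical FunCat functional annotations truncated
    to a chosen level; Markov clustering (MCL) is run on each group's
    induced PPI subnetwork; highly overlapping clusters are then merged
    through cliques of an overlap graph. Includes size-stratified
    benchmarking (recall, precision, F-measure against complex
    catalogues such as MIPS or CYC2008) and a seeded synthetic-data
    generator with planted complexes, background noise edges and
    hierarchical annotations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
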