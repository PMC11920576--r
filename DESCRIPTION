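Package: secircuit
Title: Super-Enhancer Calling and Core Regulatory Circuitry Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies super-enhancers from H3K27ac enhancer peaks by
    ROSE-style stitching and rank-curve inflection classification, integrates
    gained/lost super-enhancer gene sets with differential expression results,
    prioritises candidate genes with random-forest Gini importance and
    semantic-similarity (Friends) ranking, and maps core transcriptional
    regulatory circuitries of self-regulating transcription factors by exact
    position-weight-matrix scanning and maximal-clique enumeration. Includes a
    deterministic two-condition synthetic data generator with planted ground
    truth for end-to-end validation, and an over-representation test for gene
    set collections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
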