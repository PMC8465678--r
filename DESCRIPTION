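Package: mdlinker
Title: Stratifying Heterogeneous Types of miRNA-Disease Associations by
    Multi-Layer Network Embedding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts which of five evidence types (genetics, epigenetics,
    circulating miRNAs, tissue expression, miRNA-target interaction) link an
    miRNA to a disease. Disease-disease semantic similarity is computed on the
    MeSH-style disease hierarchy, miRNA-miRNA similarity from chaos-game
    representations of precursor sequences; node attribute vectors are learned
    with biased second-order random walks and skip-gram training; an attributed
    multi-layer heterogeneous network over the five association types is
    embedded with base + aggregated edge embeddings combined by cross-layer
    self-attention; concatenated endpoint embeddings feed a random-forest
    link-type classifier. Includes pair-level (CV-Type) and triple-level
    (CV-Triple) cross-validation protocols, consensus ranking over repeated
    stochastic runs, and seeded synthetic-data generators with planted block
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    ranger,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
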