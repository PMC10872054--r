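Package: redalph
Title: Reduced Amino-Acid Alphabets for Protein Language Models and
    Structure Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machinery for working with reduced amino-acid alphabets:
    a registry of nine published alphabets, sequence normalization and
    translation (token compression and representative-residue
    substitution), BLOSUM62 identity/similarity scoring, mutation
    distinguishability analysis, a small bidirectional-LSTM masked
    language model with the matching corruption scheme, perplexity and
    pseudo-perplexity scoring, embedding-trajectory PCA, LDDT-Calpha
    structural comparison with domain cropping, and synthetic fixture
    generators so every analysis runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
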