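Package: polsa
Title: Phrase-Ontology Latent Semantic Analysis for Literature-Based
    Knowledge Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a phrase-ontology latent semantic analysis (POLSA)
    model over a corpus of biomedical abstracts: a MeSH-style ontology and
    gene-symbol list are compiled into a multi-gram dictionary, abstracts
    are tokenized by greedy longest-match phrase matching into a sparse
    term-by-heading count matrix, the matrix is TF-IDF weighted and
    reduced by truncated singular value decomposition at a spectral-energy
    cutoff, and queries are folded into the latent space and ranked
    against ontology headings by cosine similarity.  Rankings are
    partitioned into highly associated, possibly associated and unknown
    relevance groups by one-dimensional fuzzy c-means with data-driven
    cutoffs, and relevant headings are re-attached to their ontology
    ancestor chains to form collapsible association networks exported as
    D3 flare-style JSON.  Includes a synthetic-data generator with planted
    term-heading associations so the whole pipeline is testable without
    external downloads, and a command-line interface for building models,
    querying them, and precomputing query caches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
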