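Package: ragmcnn
Title: Retrieval-Augmented Multi-Window Convolutional Classification of
    Cytokine-Inducing Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting interleukin-6 (IL-6) inducing peptides
    from per-residue protein language model embeddings. A query peptide's
    embedding matrix is enriched by retrieving the most similar peptides
    from a labeled vector store, averaging their embeddings, and fusing
    query and retrieved context at a configurable weighting ratio. The
    fused matrix is classified by a multi-window one-dimensional
    convolutional network (parallel kernels of different extents, global
    max pooling, concatenation, sigmoid output). Includes a deterministic
    synthetic embedder and planted-motif dataset generator for testing, an
    adapter interface for real protein language models, a full evaluation
    harness (sensitivity, specificity, accuracy, balanced accuracy,
    Matthews correlation coefficient, ROC-AUC, stratified k-fold
    cross-validation), ablation sweeps over window sizes, filter counts
    and fusion ratios, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
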