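Package: markerAttn
Type: Package
Title: Marker-Gene Cell Type Annotation with a Pathway-Masked Attention
    Classifier
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Annotates single-cell RNA-seq data with cell types using only
    a marker-gene catalog, no labelled training cells. Cell-type relevance
    scores computed from marker genes (six strategies, including a
    specificity-weighted z-score method) are normalized into soft
    pseudo-labels, a single-layer multi-head attention classifier whose
    token embedding is masked by pathway membership is pretrained on them
    with a Kullback-Leibler objective, and the classifier is then refined
    by iterative self-training on its own predictions. The attention paid
    by the class token to each pathway provides an interpretable per-cell
    pathway profile that can be clustered and tested for signature
    pathways. A seeded negative-binomial simulator with planted cell
    types, markers, pathways and gene embeddings exercises the whole
    pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    nnet,
    fgsea,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
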