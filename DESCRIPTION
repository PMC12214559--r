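Package: neurescence
Title: Eigengene-Based Identification of Senescent Neurons in Single-Nucleus RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies senescent neurons (neurescence) in single-nucleus
    RNA-seq data by scoring cells against senescence gene panels with
    cell-type-balanced weighted-PCA eigengenes, labelling cells by a
    three-panel mean + 3 s.d. consensus rule, detecting overexpressed genes
    with two independent differential-expression tests (a two-part hurdle
    likelihood-ratio model and an Earth Mover's Distance permutation test),
    selecting minimal marker-gene pairs with depth-limited gain-ratio
    decision trees, and quantifying gene-set overlaps with exact
    hypergeometric and multi-set intersection statistics. A negative-binomial
    synthetic snRNA-seq generator with planted ground truth makes every
    stage testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, GeneExpression, DifferentialExpression, Classification
RoxygenNote: 7.3.3
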