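Package: femnet
Title: Functional Epigenetic Module Discovery with Cell-Type Deconvolution
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Joint analysis of promoter DNA methylation and gene expression on
    a protein-protein interaction network to discover functional epigenetic
    modules (FEMs): connected gene sets with coordinated, anti-correlated
    differential methylation and expression. Implements reference-based
    cell-type deconvolution of bulk methylomes by robust partial correlations,
    cell-fraction-adjusted moderated-t differential statistics, cell-type
    specific differential methylation via fraction-by-disease interaction
    models, seeded greedy spin-glass module growth with Monte-Carlo
    significance, and module activation (FEM-score) scoring in independent
    bulk, single-cell and surrogate-tissue cohorts. Includes a synthetic-data
    generator with known ground truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    limma,
    MASS,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
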