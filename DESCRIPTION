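Package: bcrpscreen
Title: Random-Subspace LDA Ensembles for BCRP Substrate Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Ligand-based classification of compounds as substrates or
    nonsubstrates of the breast cancer resistance protein (BCRP/ABCG2)
    efflux transporter. Implements rational clustering-based train/test
    partitioning, random-subspace ensembles of stepwise-selected linear
    discriminant functions built on block-organized conformation-independent
    (0D-2D) molecular descriptors, MAX/AVE two-model data fusion, empirical
    ROC analysis with Mann-Whitney (DeLong) variances and paired z-tests,
    partial AUC with stratified bootstrap, and early-recognition metrics
    (accumulation-curve AUC, enrichment factor, RIE, BEDROC) including a
    decoy-spiked simulated virtual-screening campaign. A synthetic-data
    generator with polyspecific (two-binding-site) label structure makes the
    whole workflow testable without proprietary descriptor software.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    pROC,
    MASS,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
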