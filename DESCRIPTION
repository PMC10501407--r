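Package: gbmQSAR
Title: 2D and 3D QSAR Modelling of Dihydropteridone PLK1 Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative structure-activity relationship (QSAR) toolkit for
    dihydropteridone-class PLK1 inhibitors assayed against glioblastoma cell
    lines. Implements heuristic forward descriptor selection with multilinear
    regression and leave-one-out cross-validation, a gene expression
    programming (GEP) symbolic-regression engine over Karva-encoded linear
    chromosomes, CoMSIA-style 3D similarity fields (steric, electrostatic,
    hydrophobic, hydrogen-bond donor/acceptor) on a regular grid modelled by
    partial least squares, external/internal validation statistics (external
    R-squared, rm-squared, Y-randomization R-squared-p), and a candidate
    design and ranking stage. A synthetic-data module generates descriptor
    matrices, activities and pseudo-aligned molecules with planted
    structure-activity relationships so every stage is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
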