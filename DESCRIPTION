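Package: phidelta
Title: Hole-Electron Excited-State Descriptors and Small-Data QSPR for
    Singlet-Oxygen Quantum Yields of Transition-Metal Photosensitizers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes excited-state hole-electron distributions and the
    derived charge-transfer descriptors (Sr, D, delta-sigma, H_CT, H, t,
    HDI, EDI) from TD-DFT configuration coefficients and Gaussian-orbital
    data evaluated on Becke-partitioned or rectilinear quadrature grids;
    assembles quantum-chemistry, molecular-structure, metal-centered and
    external-condition descriptor blocks for hexacoordinate
    transition-metal-complex photosensitizers; and fits small-data QSPR
    models of the singlet-oxygen quantum yield with six single regressors
    (SVR, KRR, GPR, XGBoost, random forest, k-NN), Shapley-based
    descriptor filtering, leave-one-out Q2 validation, delta-learning
    residual stacks and mixture-of-experts ensembles. Includes synthetic
    fixture generators (analytic Gaussian excitation systems, synthetic
    QSPR tables) so every stage is testable without electronic-structure
    calculations, plus Molden/XYZ readers and Gaussian cube export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    kernlab,
    pracma,
    ranger,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
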