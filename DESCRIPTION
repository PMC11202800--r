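Package: pdhotspot
Title: Hot-Spot Residue Prediction at Protein-DNA Binding Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts hot-spot residues at protein-DNA binding interfaces
    from per-residue structural descriptor tables. Treats short blocks of
    solvent-accessibility and secondary-structure descriptors as digital
    signals and derives empirical-mode-decomposition (EMD) statistics and
    Haar wavelet / wavelet-packet energy and entropy features from them,
    rebalances the hot/non-hot classes with SMOTE followed by Tomek-link
    cleaning, selects features with a two-step mRMR plus sequential forward
    selection search, and fits a gradient-boosted tree classifier evaluated
    by repeated stratified cross-validation. Ships a synthetic residue-table
    generator so the full pipeline is exercisable end to end without any
    external structural tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    xgboost,
    e1071,
    ranger
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
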