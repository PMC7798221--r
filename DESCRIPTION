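Package: fip
Title: Feature Interrelation Profiling of Compound Sets with Pointwise
    Mutual Information
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Profiles chemical compound sets by the pairwise co-occurrence
    of binary structural features (molecular fingerprints).  Accumulates
    feature co-occurrence relation matrices (CORM), converts them to
    co-occurrence probabilities (COPRM), pointwise mutual information
    (PMIRM) and Z-standardized PMI (ZPMIRM), and scores how tightly a
    query compound or compound set fits a reference interrelation profile
    via relative feature tightness (RFT/ZRFT).  Includes compound
    standardization and fingerprint encoding through Open Babel,
    interrelation profile histograms and exclusive-pair mining,
    compound-set overlap and average pairwise Tanimoto statistics, an
    easy/hard-to-synthesize classifier evaluation layer (ROC, AUC,
    Youden-index thresholding), and a synthetic generator of binary
    feature vectors with planted co-occurrence structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
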