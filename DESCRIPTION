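Package: pocketfp
Title: 3D Convolutional Pocket Fingerprints for Kinase Potency Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns three-dimensional structural fingerprints of kinase
    ATP-binding pockets by voxelizing prepared protein structures into
    multi-channel Gaussian density grids and training a 3D convolutional
    classifier whose flatten-layer activation (216 values) serves as a
    protein fingerprint. Combines these and other protein featurizations
    (one-hot, z-scales, ProtVec) with 1024-bit Morgan compound fingerprints
    in random-forest proteochemometric models of kinase-inhibitor potency,
    with curation of raw bioactivity records, compound-disjoint sparse and
    dense chemogenomic splits, and a full regression/classification metric
    battery. Includes a synthetic fixture generator so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    ranger,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
SystemRequirements: python3 with rdkit (compound standardization and
    Morgan fingerprints are computed through the bundled helper script)
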