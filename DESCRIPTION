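Package: condylenav
Title: Marker-Less Femoral Tunnel Navigation for ACL Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric analysis of the distal femur and arthroscopic-view
    guidance for anterior cruciate ligament reconstruction (ACLR). Provides
    CT-volume segmentation and iso-surface reconstruction, sagittal
    cutting-plane optimization by elliptical-section eccentricity and focal
    dispersion, curvature-based extraction of the capsular line reference
    (CLR) ridge on the lateral condyle, construction of the Bernard-Hertel
    4x4 grid with the ACL femoral footprint point, two-stage SIFT-ICP
    registration of arthroscopic frames to the model, semi-transparent grid
    overlay with frame-to-frame tracking, and expert-concordance metrics.
    Includes a synthetic distal-femur phantom generator with full ground
    truth so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    png,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils,
    grDevices,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
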