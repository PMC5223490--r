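Package: trabtex
Title: Grey-Level Texture Analysis of Subchondral Trabecular Bone Across CT Resolutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify subchondral trabecular bone from paired 3D
    computed-tomography acquisitions of the knee at different spatial
    resolutions. Provides a digital trabecular-bone phantom and an imaging
    simulator (Gaussian point-spread blur, partial-volume box resampling,
    additive noise) for HR-pQCT-like and clinical-CT-like geometries;
    phantom-based bone mineral density calibration and cross-device
    correction; simplified periosteal segmentation, automatic placement of
    the sixteen knee analysis volumes of interest, rigid surface
    registration with dice validation; five grey-level texture parameters
    (entropy, global and local inhomogeneity, structure-tensor anisotropy,
    semivariogram slope); and cross-modality comparison statistics
    (linear regression, Bland-Altman limits of agreement, resolution-
    dependence ratios, two-sample tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
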