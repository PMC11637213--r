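Package: phmsr
Title: Pulp-Horn Mapping-Surface Registration of Dental CBCT and Intraoral Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rigid registration of intraoral-scan crown point clouds onto
    cone-beam computed tomography (CBCT) crown and pulp point clouds for
    digitally guided root canal therapy. Implements pulp-horn feature
    mapping, moving-least-squares quadric mapping surfaces with
    point-to-surface correspondence search, a sparse iterative-closest-point
    solver (lp residual norm, ADMM), and the classic ICP, sparse ICP and
    rigid coherent-point-drift baselines. Also provides the CBCT
    preprocessing front-end (hybrid wavelet/non-local-means filtering,
    adaptive spiking-cortical-model tooth and pulp segmentation, isosurface
    extraction), oriented-bounding-box crown equivalence cropping,
    crown-pulp pose-deviation metrics (RMSE, CPPD, CPOD), synthetic tooth
    phantom generators, and STL/PLY/DICOM input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
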