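Package: vertseg
Title: Patch-Based Combined Localization and Instance Segmentation of
    Vertebrae in CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual lumbar and thoracic vertebra instance segmentation
    for 3D CT volumes. A single compact convolutional network processes
    overlapping volume patches and jointly emits a three-label semantic
    segmentation (background, inner body, boundary shell) and up to three
    vertebra-center predictions with confidence scores. Accumulated center
    votes are clustered by weighted k-means; the vertebra count is selected
    by maximizing a clustering score built from per-level Gaussian models of
    inter-vertebral z-distances; instances are separated by a seeded
    watershed on a signed distance map, with recovery of missed vertebrae
    and island/hole cleanup. Includes a synthetic spine phantom generator,
    surface-distance segmentation metrics, and NIfTI input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
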