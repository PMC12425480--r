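Package: granametrics
Title: Quantitative Membrane Architecture Analysis for Thylakoid Cryo-Electron Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the membrane architecture of chloroplast
    thylakoid networks from cryo-electron tomograms and segmentations:
    classification of appressed versus non-appressed membrane domains by
    normal-ray tracing on triangle meshes, sub-nanometer spacing morphometrics
    from normal-direction intensity profiles (membrane thickness, stromal gap,
    lumen width, thylakoid thickness), surface point-pattern statistics of
    photosynthetic complexes (geodesic nearest neighbors, distance-to-edge
    binning), and supercomplex footprint occupancy, clash, and cross-membrane
    overlap. Includes a synthetic phantom generator with known ground truth
    (multilamellar grana stacks, hard-core surface point processes), readers
    and writers for MRC volumes, STAR particle tables, and OBJ meshes, and an
    end-to-end reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    rlang,
    yaml,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    bio3d,
    withr
Config/testthat/edition: 3
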