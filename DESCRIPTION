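Package: nichemetry
Title: Scaffold Niche Geometry, Spectral Unmixing and Cell Motility
    Analysis for 3D Microscaffold Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how microfabricated scaffold geometry
    shapes the packing and motility of cultured cells. Provides a
    parametric model of graded wall-and-niche scaffolds with closed-form
    chamber footprints, openings and isotropic niche-occupancy
    expectations; a synthetic hyperspectral confocal image generator with
    known ground truth; ROI-based endmember estimation and per-voxel
    linear unmixing (ordinary and non-negative least squares) to separate
    scaffold autofluorescence from stained-cell fluorescence; per-chamber
    cell-packing statistics against the isotropic expectation; an
    exponential photobleaching (UV-quench) model with log-linear fitting;
    and a radius-kernel greedy nearest-neighbour nucleus tracker with
    multi-pass recovery, track filtering and motility gradient maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
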