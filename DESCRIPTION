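Package: microtract
Title: Tensor Field Imaging and Tractography for 3D Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds orientation tensor-field representations of segmented 3D
    fluorescence microscopy volumes. Binary vascular masks are thinned to a
    medial-axis skeleton and converted to a node/branch graph; inter-node
    segments (or per-cell principal axes from label volumes) become oriented
    feature descriptors whose endpoint clouds are pooled in a sliding cubic
    window to form per-voxel 3x3 variance-covariance tensors. Eigen-analysis
    of the tensor field yields fractional anisotropy, Westin shape
    coefficients, directionally encoded color maps, helix/transverse angle
    maps in a cylindrical wall frame, and deterministic second-order
    Runge-Kutta streamline tractograms with an angular termination criterion.
    Includes phantom generators (helical vascular shells, oriented ellipsoid
    cell populations) with exact ground truth, and readers/writers for TIFF
    stacks, NRRD tensor volumes, TrackVis streamlines, GraphML/CSV skeleton
    graphs and VTK glyph polydata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    tiff,
    png,
    yaml,
    MASS,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    xml2
Config/testthat/edition: 3
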