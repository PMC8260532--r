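Package: trident3d
Title: Freehand 3D Photoacoustic Image Compounding from an Optical Trident Pattern
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sensorless 2D-to-3D reconstruction of freehand
    photoacoustic tomography scans. A printed optical trident pattern on the
    skin appears as three bright absorption peaks in every tomographic slice;
    the spacing of the peaks encodes the pose (tilt angle and offset along the
    pattern) of the imaging plane in the pattern coordinate frame. The package
    extracts the peaks, estimates per-slice rigid poses, compounds the posed
    slices into a voxel volume by nearest-voxel averaging, and quantifies
    reconstruction quality with iterative-closest-point registration against a
    reference wire model (fiducial registration error) and a slice-based mean
    vessel distance. A synthetic scan simulator with exact ray-line
    intersection geometry, N-wire and vessel phantoms, and freehand trajectory
    models provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    tiff,
    yaml,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
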