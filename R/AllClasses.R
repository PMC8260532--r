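#' @import methods
NULL

#' Trident pattern geometry
#'
#' Describes the optical trident fiducial: an isosceles triangle (the two
#' "tilted lines") plus its apex-angle bisector (the "central line").  The
#' pattern coordinate frame is right-handed with the central line along +z,
#' the lateral direction along +x and tissue depth along +y; the pattern
#' itself lies in the plane y = 0 with its apex at the origin.  The tilted
#' lines are x = +/- tanGamma * z for z in [0, a0Max].
#'
#' @slot tanGamma half-opening slope of the trident (dimensionless).
#' @slot dMax full opening distance at the far end of the pattern (mm);
#'   equals `2 * tanGamma * a0Max`.
#' @slot a0Max vertical extent of the pattern along the central line (mm).
#' @slot patternWavelength wavelength at which the pattern ink absorbs (nm).
#' @slot targetWavelength wavelength used for the tissue target (nm).
#' @slot a0GateMargin fractional tolerance by which a decoded offset may
#'   exceed `a0Max` before the slice is rejected (default 0.1).
#'
#' @seealso [patternSpec()] for the user-facing constructor.
#' @export
setClass("PatternSpec",
  representation(
    tanGamma = "numeric",
    dMax = "numeric",
    a0Max = "numeric",
    patternWavelength = "numeric",
    targetWavelength = "numeric",
    a0GateMargin = "numeric"
  )
)

setValidity("PatternSpec", function(object) {
  msg <- character()
  if (length(object@tanGamma) != 1L || !is.finite(object@tanGamma) ||
      object@tanGamma <= 0)
    msg <- c(msg, "'tanGamma' must be a single positive number")
  if (object@dMax <= 0) msg <- c(msg, "'dMax' must be positive")
  if (object@a0Max <= 0) msg <- c(msg, "'a0Max' must be positive")
  if (abs(object@tanGamma - object@dMax / (2 * object@a0Max)) > 1e-9)
    msg <- c(msg, "'tanGamma' must equal dMax / (2 * a0Max)")
  if (object@patternWavelength <= 0 || object@targetWavelength <= 0)
    msg <- c(msg, "wavelengths must be positive")
  if (object@patternWavelength == object@targetWavelength)
    msg <- c(msg, "pattern and target wavelengths must be distinct")
  if (object@a0GateMargin < 0)
    msg <- c(msg, "'a0GateMargin' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Per-slice probe pose in the pattern frame
#'
#' The three degrees of freedom a single slice of the trident encodes: the
#' slice tilt `alpha` (radians, signed), the offset `a0` of the slice's
#' central-line intersection from the pattern origin (mm), and the image
#' coordinates `xc`, `yc` (mm) of the central pattern peak, which anchor the
#' image plane to the pattern frame.
#'
#' @slot alpha slice tilt angle in radians; |alpha| < pi/2.
#' @slot a0 offset along the central line (mm); > 0 for in-pattern poses.
#' @slot xc,yc image-plane coordinates of the central peak (mm).
#' @export
setClass("ProbePose",
  representation(alpha = "numeric", a0 = "numeric", xc = "numeric",
                 yc = "numeric")
)

setValidity("ProbePose", function(object) {
  msg <- character()
  for (s in c("alpha", "a0", "xc", "yc"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  if (!length(msg) && abs(object@alpha) >= pi / 2)
    msg <- c(msg, "|alpha| must be < pi/2")
  if (length(msg)) msg else TRUE
})

#' Rigid 4x4 homogeneous transform
#'
#' A rigid-body transform with translations in mm.  The rotation block is
#' orthonormal with determinant +1 and the last row is (0, 0, 0, 1).
#'
#' @slot matrix the 4x4 homogeneous matrix.
#' @export
setClass("RigidTransform", representation(matrix = "matrix"))

setValidity("RigidTransform", function(object) {
  m <- object@matrix
  if (!is.numeric(m) || !identical(dim(m), c(4L, 4L)))
    return("'matrix' must be a numeric 4x4 matrix")
  if (any(!is.finite(m))) return("'matrix' must be finite")
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation block is not orthonormal")
  if (abs(det(R) - 1) > 1e-9)
    return("rotation block must have determinant +1")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 0)
    return("last row must be (0, 0, 0, 1)")
  TRUE
})

#' A two-channel photoacoustic slice
#'
#' One co-registered two-wavelength tomographic image.  Channels are stored
#' as matrices with rows indexing axial depth (image y, increasing away from
#' the transducer) and columns indexing the lateral direction (image x).
#' The pixel at row i, column j has image coordinates
#' x = (j-1) * spacing\["lateral"\], y = (i-1) * spacing\["axial"\] (mm).
#'
#' @slot patternChannel intensity image at the pattern wavelength.
#' @slot targetChannel intensity image at the target wavelength.
#' @slot pixelSpacing named numeric of length 2, `c(lateral=, axial=)` in mm.
#' @slot index acquisition-order index (integer).
#' @export
setClass("PASlice",
  representation(patternChannel = "matrix", targetChannel = "matrix",
                 pixelSpacing = "numeric", index = "integer")
)

setValidity("PASlice", function(object) {
  msg <- character()
  if (!identical(dim(object@patternChannel), dim(object@targetChannel)))
    msg <- c(msg, "channels must have identical dimensions")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    msg <- c(msg, "'pixelSpacing' must be two positive numbers (lateral, axial)")
  if (length(msg)) msg else TRUE
})

#' Compounded voxel volume
#'
#' A 3D voxel grid in the pattern frame.  `values` holds the per-voxel mean
#' of all image pixels assigned to that voxel; `counts` the number of
#' contributing pixels.  Voxel (i, j, k) (1-based) is centred at
#' `origin + (i-1, j-1, k-1) * spacing`, with axes (x, y, z) of the pattern
#' frame.
#'
#' @slot origin physical position of the first voxel centre (mm, length 3).
#' @slot spacing voxel edge lengths (mm, length 3, positive).
#' @slot values 3D numeric array of mean intensities.
#' @slot counts 3D integer-valued array of contribution counts.
#' @export
setClass("VoxelVolume",
  representation(origin = "numeric", spacing = "numeric",
                 values = "array", counts = "array")
)

setValidity("VoxelVolume", function(object) {
  msg <- character()
  if (length(object@origin) != 3L) msg <- c(msg, "'origin' must have length 3")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive numbers")
  if (!identical(dim(object@values), dim(object@counts)))
    msg <- c(msg, "'values' and 'counts' must have identical dimensions")
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3D array")
  if (!length(msg)) {
    if (any(object@counts < 0)) msg <- c(msg, "'counts' must be non-negative")
    if (any(object@values[object@counts == 0] != 0))
      msg <- c(msg, "'values' must be zero wherever 'counts' is zero")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic phantom
#'
#' A collection of 3D primitives in the pattern frame: straight wire
#' segments (with a diameter) and/or curved tubes (a centreline polyline
#' with a radius).  Used by the scan simulator to render target-channel
#' intensity and to export ground-truth reference models.
#'
#' @slot segments list of wire segments; each a list with `from`, `to`
#'   (length-3 mm), `diameter` (mm) and `intensity`.
#' @slot tubes list of tubes; each a list with `centerline` (n x 3 matrix,
#'   mm), `radius` (mm) and `intensity`.
#' @slot boundingBox 2 x 3 matrix (min row, max row) enclosing all primitives.
#' @export
setClass("Phantom",
  representation(segments = "list", tubes = "list", boundingBox = "matrix")
)

setValidity("Phantom", function(object) {
  if (length(object@segments) == 0L && length(object@tubes) == 0L)
    return("phantom must contain at least one primitive")
  for (s in object@segments)
    if (s$diameter <= 0) return("segment diameters must be positive")
  for (tb in object@tubes)
    if (tb$radius <= 0) return("tube radii must be positive")
  TRUE
})

#' A simulated freehand scan with ground truth
#'
#' @slot slices list of [PASlice-class] objects in acquisition order.
#' @slot truthPoses data.frame with one row per slice: columns `index`,
#'   `alpha`, `a0`, `xc`, `yc`, `tilt` (out-of-plane tilt, radians).
#' @slot truthModel n x 3 matrix of reference model points (mm).
#' @slot config list echoing the full simulation configuration.
#' @export
setClass("SyntheticScan",
  representation(slices = "list", truthPoses = "data.frame",
                 truthModel = "matrix", config = "list")
)

setValidity("SyntheticScan", function(object) {
  if (length(object@slices) != nrow(object@truthPoses))
    return("one truth pose per slice required")
  if (nrow(object@truthModel) == 0L)
    return("'truthModel' must be non-empty")
  TRUE
})
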