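#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param object an object of one of the package's classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patternChannel", function(object) standardGeneric("patternChannel"))
#' @rdname accessors
#' @export
setGeneric("targetChannel", function(object) standardGeneric("targetChannel"))
#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setGeneric("sliceIndex", function(object) standardGeneric("sliceIndex"))
#' @rdname accessors
#' @export
setGeneric("voxelValues", function(object) standardGeneric("voxelValues"))
#' @rdname accessors
#' @export
setGeneric("voxelCounts", function(object) standardGeneric("voxelCounts"))
#' @rdname accessors
#' @export
setGeneric("voxelOrigin", function(object) standardGeneric("voxelOrigin"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("transformMatrix", function(object) standardGeneric("transformMatrix"))
#' @rdname accessors
#' @export
setGeneric("scanSlices", function(object) standardGeneric("scanSlices"))
#' @rdname accessors
#' @export
setGeneric("truthPoses", function(object) standardGeneric("truthPoses"))
#' @rdname accessors
#' @export
setGeneric("truthModel", function(object) standardGeneric("truthModel"))

#' @rdname accessors
#' @export
setMethod("patternChannel", "PASlice", function(object) object@patternChannel)
#' @rdname accessors
#' @export
setMethod("targetChannel", "PASlice", function(object) object@targetChannel)
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "PASlice", function(object) object@pixelSpacing)
#' @rdname accessors
#' @export
setMethod("sliceIndex", "PASlice", function(object) object@index)
#' @rdname accessors
#' @export
setMethod("voxelValues", "VoxelVolume", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("voxelCounts", "VoxelVolume", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("voxelOrigin", "VoxelVolume", function(object) object@origin)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VoxelVolume", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("transformMatrix", "RigidTransform", function(object) object@matrix)
#' @rdname accessors
#' @export
setMethod("scanSlices", "SyntheticScan", function(object) object@slices)
#' @rdname accessors
#' @export
setMethod("truthPoses", "SyntheticScan", function(object) object@truthPoses)
#' @rdname accessors
#' @export
setMethod("truthModel", "SyntheticScan", function(object) object@truthModel)

setMethod("show", "PatternSpec", function(object) {
  cat("PatternSpec: trident fiducial geometry\n")
  cat(sprintf("  tan(gamma) = %.4g  (opening %.3g mm over extent %.3g mm)\n",
              object@tanGamma, object@dMax, object@a0Max))
  cat(sprintf("  wavelengths: pattern %g nm, target %g nm\n",
              object@patternWavelength, object@targetWavelength))
  cat(sprintf("  a0 gate margin: %g%%\n", 100 * object@a0GateMargin))
})

setMethod("show", "ProbePose", function(object) {
  cat(sprintf("ProbePose: alpha = %.3f deg, a0 = %.3f mm, centre (%.3f, %.3f) mm\n",
              object@alpha * 180 / pi, object@a0, object@xc, object@yc))
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform (mm):\n")
  print(round(object@matrix, 6))
})

setMethod("show", "PASlice", function(object) {
  d <- dim(object@patternChannel)
  cat(sprintf("PASlice #%d: %d x %d px (axial x lateral), spacing %.3g x %.3g mm\n",
              object@index, d[1], d[2],
              object@pixelSpacing[1], object@pixelSpacing[2]))
})

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelVolume: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  origin (%.3g, %.3g, %.3g) mm; %d filled voxels\n",
              object@origin[1], object@origin[2], object@origin[3],
              sum(object@counts > 0)))
})

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom: %d wire segment(s), %d tube(s)\n",
              length(object@segments), length(object@tubes)))
})

setMethod("show", "SyntheticScan", function(object) {
  cat(sprintf("SyntheticScan: %d slices, %d reference model points\n",
              length(object@slices), nrow(object@truthModel)))
})
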