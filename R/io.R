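## File formats: NIfTI / multi-page TIFF slice stacks with a JSON sidecar,
## NIfTI volumes, CSV pose tables and point clouds, ascii PLY, YAML configs.

#' Write a slice stack to disk
#'
#' Writes the two channels as NIfTI files (`pattern.nii.gz`,
#' `target.nii.gz`; rows x columns x slices) or multi-page TIFF
#' (`pattern.tif`, `target.tif`), plus a JSON sidecar `stack.json` with the
#' pixel spacing, wavelengths and acquisition order.
#'
#' @param slices list of [PASlice-class] objects.
#' @param dir output directory (created if missing).
#' @param format `"nifti"` or `"tiff"`.
#' @param pattern optional [PatternSpec-class] whose wavelengths are
#'   recorded in the sidecar.
#' @return `dir`, invisibly.
#' @export
writeSliceStack <- function(slices, dir, format = c("nifti", "tiff"),
                            pattern = NULL) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- slices[[1L]]@pixelSpacing
  patArr <- simplify2array(lapply(slices, function(s) s@patternChannel))
  tgtArr <- simplify2array(lapply(slices, function(s) s@targetChannel))
  if (format == "nifti") {
    for (ch in c("pattern", "target")) {
      arr <- if (ch == "pattern") patArr else tgtArr
      img <- RNifti::asNifti(arr)
      RNifti::pixdim(img) <- c(ps[["axial"]], ps[["lateral"]], 1)
      RNifti::writeNifti(img, file.path(dir, paste0(ch, ".nii.gz")))
    }
  } else {
    # TIFF stores [0,1]; images are already non-negative, scale by max
    sc <- max(patArr, tgtArr, 1e-12)
    tiff::writeTIFF(lapply(slices, function(s)
      pmax(s@patternChannel, 0) / sc), file.path(dir, "pattern.tif"),
      bits.per.sample = 16L)
    tiff::writeTIFF(lapply(slices, function(s)
      pmax(s@targetChannel, 0) / sc), file.path(dir, "target.tif"),
      bits.per.sample = 16L)
  }
  sidecar <- list(format = format,
                  pixel_spacing_mm = list(lateral = ps[["lateral"]],
                                          axial = ps[["axial"]]),
                  n_slices = length(slices),
                  acquisition_order = vapply(slices, function(s) s@index,
                                             integer(1)),
                  pattern_wavelength_nm =
                    if (is.null(pattern)) NA else pattern@patternWavelength,
                  target_wavelength_nm =
                    if (is.null(pattern)) NA else pattern@targetWavelength)
  jsonlite::write_json(sidecar, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a slice stack written by [writeSliceStack()]
#'
#' @param dir directory holding the channel files and `stack.json`.
#' @return list of [PASlice-class] objects in acquisition order.
#' @export
readSliceStack <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  ps <- c(lateral = side$pixel_spacing_mm$lateral,
          axial = side$pixel_spacing_mm$axial)
  if (identical(side$format, "nifti")) {
    pat <- as.array(RNifti::readNifti(file.path(dir, "pattern.nii.gz")))
    tgt <- as.array(RNifti::readNifti(file.path(dir, "target.nii.gz")))
    n <- dim(pat)[3]
    lapply(seq_len(n), function(i)
      paSlice(pat[, , i], tgt[, , i], ps, side$acquisition_order[i]))
  } else {
    pat <- tiff::readTIFF(file.path(dir, "pattern.tif"), all = TRUE)
    tgt <- tiff::readTIFF(file.path(dir, "target.tif"), all = TRUE)
    lapply(seq_along(pat), function(i)
      paSlice(pat[[i]], tgt[[i]], ps, side$acquisition_order[i]))
  }
}

#' Write a compounded volume as NIfTI
#'
#' The affine (sform) encodes voxel spacing and origin in mm.  The
#' contribution counts can be written alongside as a second NIfTI.
#'
#' @param volume a [VoxelVolume-class].
#' @param path output `.nii.gz` path.
#' @param countsPath optional path for the counts volume.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path, countsPath = NULL) {
  writeOne <- function(arr, p) {
    img <- RNifti::asNifti(arr)
    aff <- rbind(cbind(diag(volume@spacing), volume@origin), c(0, 0, 0, 1))
    RNifti::sform(img) <- structure(aff, code = 2L)  # also sets pixdim
    RNifti::writeNifti(img, p)
  }
  writeOne(volume@values, path)
  if (!is.null(countsPath)) writeOne(volume@counts, countsPath)
  invisible(path)
}

#' Read a volume written by [writeVolume()]
#'
#' @param path `.nii.gz` path.
#' @param countsPath optional counts NIfTI; if missing, counts are 1 where
#'   values are nonzero.
#' @return a [VoxelVolume-class].
#' @export
readVolume <- function(path, countsPath = NULL) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  values <- array(as.numeric(img), dim = dim(img))
  counts <- if (!is.null(countsPath)) {
    cimg <- RNifti::readNifti(countsPath)
    array(as.numeric(cimg), dim = dim(cimg))
  } else array(as.integer(values != 0), dim = dim(values))
  new("VoxelVolume", origin = as.numeric(aff[1:3, 4]),
      spacing = as.numeric(diag(aff)[1:3]),
      values = values, counts = counts)
}

#' Write / read a per-slice pose table
#'
#' CSV with columns `index`, `alpha_deg`, `a0_mm`, `x_c_mm`, `y_c_mm`,
#' `accepted`, `rejection_reason`.
#'
#' @param poses data.frame as produced by [stackPoses()] (or the truth
#'   poses of a [SyntheticScan-class], converted to the same columns).
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read), invisibly for write.
#' @export
writePoseTable <- function(poses, path) {
  cols <- c("index", "alpha_deg", "a0_mm", "x_c_mm", "y_c_mm", "accepted",
            "rejection_reason")
  if (!"accepted" %in% names(poses)) poses$accepted <- TRUE
  if (!"rejection_reason" %in% names(poses))
    poses$rejection_reason <- NA_character_
  if (!"alpha_deg" %in% names(poses) && "alpha" %in% names(poses)) {
    poses$alpha_deg <- poses$alpha * 180 / pi
    poses$a0_mm <- poses$a0
    poses$x_c_mm <- poses$xc
    poses$y_c_mm <- poses$yc
  }
  utils::write.csv(poses[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePoseTable
#' @export
readPoseTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read point clouds
#'
#' `writePointsPLY()` writes an ascii PLY with x/y/z float properties (mm);
#' `writePointsCSV()` writes a CSV with columns `x_mm`, `y_mm`, `z_mm`.
#'
#' @param points n x 3 matrix (mm).
#' @param path output path.
#' @return `path` (write) or an n x 3 matrix (read).
#' @export
writePointsPLY <- function(points, path) {
  points <- asPointMatrix(points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(points)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  utils::write.table(format(points, scientific = FALSE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writePointsPLY
#' @export
readPointsPLY <- function(path) {
  lines <- readLines(path)
  endHdr <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  dat <- utils::read.table(text = lines[(endHdr + 1):(endHdr + nv)])
  unname(as.matrix(dat[, 1:3]))
}

#' @rdname writePointsPLY
#' @export
writePointsCSV <- function(points, path) {
  points <- asPointMatrix(points)
  utils::write.csv(data.frame(x_mm = points[, 1], y_mm = points[, 2],
                              z_mm = points[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePointsPLY
#' @export
readPointsCSV <- function(path) {
  unname(as.matrix(utils::read.csv(path)[, 1:3]))
}

#' Read / write a pattern configuration YAML
#'
#' Keys: `d_max_mm`, `a0_max_mm` (or `tan_gamma` directly),
#' `pattern_wavelength_nm`, `target_wavelength_nm`, `a0_gate_margin`.
#'
#' @param path YAML file path.
#' @return a [PatternSpec-class] (read); `path` invisibly (write).
#' @export
readPatternConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  patternSpec(
    dMax = cfg$d_max_mm %||% 20,
    a0Max = cfg$a0_max_mm %||% 50,
    tanGamma = cfg$tan_gamma,
    patternWavelength = cfg$pattern_wavelength_nm %||% 750,
    targetWavelength = cfg$target_wavelength_nm %||% 850,
    a0GateMargin = cfg$a0_gate_margin %||% 0.1)
}

#' @rdname readPatternConfig
#' @param pattern a [PatternSpec-class] to serialise.
#' @export
writePatternConfig <- function(pattern, path) {
  yaml::write_yaml(list(d_max_mm = pattern@dMax, a0_max_mm = pattern@a0Max,
                        tan_gamma = pattern@tanGamma,
                        pattern_wavelength_nm = pattern@patternWavelength,
                        target_wavelength_nm = pattern@targetWavelength,
                        a0_gate_margin = pattern@a0GateMargin), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
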