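## Nearest-voxel compounding of posed slices into a 3D grid.

#' Compound posed slices into a voxel volume
#'
#' Transforms every pixel centre of every slice's target channel into the
#' pattern frame and assigns it to the nearest voxel of a grid covering the
#' bounding box of all transformed pixels.  A voxel's value is the mean of
#' all pixels assigned to it; contribution counts are retained.  In-plane
#' voxel spacing equals the slice pixel spacing; the out-of-plane (z)
#' spacing is either given or derived from the probe motion as the median
#' |change in slice z-position| between consecutive slices, clamped to
#' \[0.1, 2\] mm.
#'
#' Nearest-voxel assignment uses round-half-up per axis:
#' `index = floor((coord - origin) / spacing + 0.5)`, which is
#' deterministic and consistent under grid translation.
#'
#' @param slices list of [PASlice-class] objects (target channel is
#'   compounded).
#' @param transforms list of [RigidTransform-class], one per slice.
#' @param zSpacing out-of-plane voxel size in mm, or `"auto"`.
#' @param channel `"target"` (default) or `"pattern"`.
#' @return a [VoxelVolume-class].
#' @export
compoundVolume <- function(slices, transforms, zSpacing = "auto",
                           channel = c("target", "pattern")) {
  channel <- match.arg(channel)
  if (length(slices) == 0L)
    t3dError("no slices to compound", "emptyInputError")
  if (length(slices) != length(transforms))
    t3dError("need exactly one transform per slice", "domainError")
  ps <- slices[[1L]]@pixelSpacing
  dxy <- c(ps[["lateral"]], ps[["axial"]])

  pts <- vector("list", length(slices))
  vals <- vector("list", length(slices))
  centerZ <- numeric(length(slices))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    img <- if (channel == "target") s@targetChannel else s@patternChannel
    nr <- nrow(img); nc <- ncol(img)
    xs <- (seq_len(nc) - 1) * s@pixelSpacing[["lateral"]]
    ys <- (seq_len(nr) - 1) * s@pixelSpacing[["axial"]]
    pix <- cbind(rep(xs, each = nr), rep(ys, times = nc), 0)
    pts[[i]] <- transformPoints(transforms[[i]], pix)
    vals[[i]] <- as.vector(img)
    ctr <- transformPoints(transforms[[i]],
                           matrix(c(xs[ceiling(nc / 2)], ys[ceiling(nr / 2)], 0), 1))
    centerZ[i] <- ctr[3]
  }
  if (identical(zSpacing, "auto")) {
    dz <- if (length(slices) > 1L) stats::median(abs(diff(centerZ))) else 1
    zSpacing <- min(2, max(0.1, dz))
  }
  spacing <- c(dxy, zSpacing)

  P <- do.call(rbind, pts)
  v <- unlist(vals, use.names = FALSE)
  lo <- apply(P, 2, min)
  origin <- lo
  idx <- floor(sweep(sweep(P, 2, origin), 2, spacing, "/") + 0.5)
  dims <- apply(idx, 2, max) + 1L
  lin <- idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3]) + 1
  n <- prod(dims)
  counts <- tabulate(lin, nbins = n)
  sums <- numeric(n)
  agg <- rowsum(v, lin)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  values <- ifelse(counts > 0, sums / pmax(counts, 1L), 0)
  new("VoxelVolume", origin = as.numeric(origin),
      spacing = as.numeric(spacing),
      values = array(values, dim = dims),
      counts = array(counts, dim = dims))
}

#' Threshold segmentation of a volume into a point cloud
#'
#' Returns the physical centres of all voxels whose value exceeds the
#' background-suppressing threshold (and which received at least one
#' pixel).
#'
#' @param volume a [VoxelVolume-class].
#' @param threshold intensity threshold; voxels with `value > threshold`
#'   are kept.  May also be given as a fraction of the maximum via
#'   `relative = TRUE`.
#' @param relative if `TRUE`, `threshold` is a fraction of `max(values)`.
#' @return n x 3 matrix of voxel-centre coordinates (mm); possibly empty.
#' @export
thresholdSegment <- function(volume, threshold, relative = FALSE) {
  stopifnot(is(volume, "VoxelVolume"))
  if (!is.finite(threshold)) t3dError("threshold must be finite", "domainError")
  if (relative) threshold <- threshold * max(volume@values)
  keep <- which(volume@values > threshold & volume@counts > 0, arr.ind = TRUE)
  if (nrow(keep) == 0L) return(matrix(numeric(), 0L, 3L))
  sweep(sweep(keep - 1, 2, volume@spacing, "*"), 2, volume@origin, "+") |>
    unname()
}

#' Voxel-centre coordinates of a volume's filled voxels
#'
#' @param volume a [VoxelVolume-class].
#' @return n x 3 matrix of coordinates (mm) of voxels with count > 0.
#' @export
filledVoxelCenters <- function(volume) {
  thresholdSegment(volume, -Inf)
}
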