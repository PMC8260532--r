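## Quantitative validation: ICP + FRE, mean vessel distance, and the
## curved-surface (Bezier) discrepancy analysis.

#' Root-mean-square fiducial registration error
#'
#' RMS of the Euclidean distances between corresponding points.
#'
#' @param source,target n x 3 matrices of matched points (row i of
#'   `source` corresponds to row i of `target`).
#' @return RMS distance (mm).
#' @export
fre <- function(source, target) {
  source <- asPointMatrix(source); target <- asPointMatrix(target)
  if (nrow(source) == 0L || nrow(source) != nrow(target))
    t3dError("need a non-empty matched correspondence set", "domainError")
  sqrt(mean(rowSums((source - target)^2)))
}

## closed-form least-squares rigid fit (Kabsch/Umeyama via SVD)
fitRigid <- function(source, target) {
  cs <- colMeans(source); ct <- colMeans(target)
  H <- crossprod(sweep(source, 2, cs), sweep(target, 2, ct))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigidTransform(R, ct - as.vector(R %*% cs))
}

#' Iterative closest point registration
#'
#' Point-to-point ICP: alternate exact nearest-neighbour correspondence
#' (source to target) with the closed-form SVD rigid update, until the
#' change in FRE between two iterations falls below `stopDelta` or
#' `maxIter` is reached.  No outlier trimming is applied.
#'
#' @param source n x 3 matrix; the cloud that is moved.
#' @param target m x 3 matrix; the fixed reference cloud.
#' @param stopDelta convergence threshold on |change in FRE| (mm).
#' @param maxIter iteration cap.
#' @return list with `transform` ([RigidTransform-class] mapping source
#'   onto target), `fre` (mm), `iterations`, `freTrace` (mm per iteration)
#'   and `converged` (`TRUE` if the stop rule fired before `maxIter`).
#' @export
icpRegister <- function(source, target, stopDelta = 0.001, maxIter = 200L) {
  source <- asPointMatrix(source); target <- asPointMatrix(target)
  if (nrow(source) < 3L || nrow(target) < 3L)
    t3dError("both clouds need at least 3 points", "degenerateInputError")
  if (qr(sweep(source, 2, colMeans(source)))$rank < 2L ||
      qr(sweep(target, 2, colMeans(target)))$rank < 2L)
    t3dError("clouds must be non-collinear", "degenerateInputError")
  moved <- source
  Tacc <- diag(4)
  trace <- numeric()
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    nn <- nnMatch(moved, target)
    corr <- target[nn$index, , drop = FALSE]
    f <- fre(moved, corr)
    trace <- c(trace, f)
    if (it > 1L && abs(trace[it - 1L] - f) < stopDelta) { converged <- TRUE; break }
    if (f == 0) { converged <- TRUE; break }
    Tup <- fitRigid(moved, corr)
    moved <- transformPoints(Tup, moved)
    Tacc <- Tup@matrix %*% Tacc
  }
  list(transform = new("RigidTransform", matrix = Tacc),
       fre = trace[length(trace)], iterations = length(trace),
       freTrace = trace, converged = converged)
}

#' Extract per-slice vessel centres from a set of volumes
#'
#' For every z plane of every volume, the vessel centre is located with the
#' same 1D peak detector used for the pattern peaks, applied separably: the
#' plane is collapsed by maximum onto each in-plane axis and the most
#' prominent peak of each profile gives the (x, y) centre.  A z position is
#' eligible when at least `minScans` volumes yield a centre there.
#'
#' @param volumes list of [VoxelVolume-class] objects on a common z grid.
#' @param minScans eligibility threshold (volumes per position).
#' @param minProminence passed to [detectPeaks()].
#' @return list with `centers` (data.frame: `zIndex`, `scan`, `x`, `y`,
#'   `z`, all physical mm except the indices) and `eligible` (logical per
#'   z index).
#' @export
extractVesselCenters <- function(volumes, minScans = 7L,
                                 minProminence = NULL) {
  if (length(volumes) == 0L) t3dError("need at least one volume", "domainError")
  nz <- min(vapply(volumes, function(v) dim(v@values)[3], integer(1)))
  rows <- list()
  for (s in seq_along(volumes)) {
    vol <- volumes[[s]]
    for (k in seq_len(nz)) {
      plane <- vol@values[, , k]
      if (all(plane <= 0)) next
      # collapse onto x (dim 1) and y (dim 2) by maximum
      profX <- apply(plane, 1, max)
      profY <- apply(plane, 2, max)
      pkX <- detectPeaks(profX, minProminence, minSeparation = vol@spacing[1],
                         spacing = vol@spacing[1])
      pkY <- detectPeaks(profY, minProminence, minSeparation = vol@spacing[2],
                         spacing = vol@spacing[2])
      if (nrow(pkX) == 0L || nrow(pkY) == 0L) next
      cx <- pkX$lateral[which.max(pkX$prominence)] + vol@origin[1]
      cy <- pkY$lateral[which.max(pkY$prominence)] + vol@origin[2]
      rows[[length(rows) + 1L]] <-
        data.frame(zIndex = k, scan = s, x = cx, y = cy,
                   z = vol@origin[3] + (k - 1) * vol@spacing[3])
    }
  }
  centers <- if (length(rows)) do.call(rbind, rows)
    else data.frame(zIndex = integer(), scan = integer(), x = numeric(),
                    y = numeric(), z = numeric())
  tab <- table(factor(centers$zIndex, levels = seq_len(nz)))
  eligible <- as.vector(tab) >= minScans
  list(centers = centers, eligible = eligible, minScans = minScans)
}

#' Mean vessel distance
#'
#' Precision (reproducibility) metric across repeated scans: for every
#' eligible z position the reference is the mean of the available centres,
#' and the MVD is the mean Euclidean distance of the individual centres to
#' their position's reference, averaged over all (position, scan) pairs.
#'
#' @param centerSet result of [extractVesselCenters()].
#' @return MVD in mm.
#' @export
mvd <- function(centerSet) {
  el <- which(centerSet$eligible)
  cc <- centerSet$centers
  cc <- cc[cc$zIndex %in% el, , drop = FALSE]
  if (nrow(cc) == 0L)
    t3dError("no eligible positions for MVD", "emptyInputError")
  d <- unlist(lapply(split(cc, cc$zIndex), function(g) {
    ref <- c(mean(g$x), mean(g$y))
    sqrt((g$x - ref[1])^2 + (g$y - ref[2])^2)
  }), use.names = FALSE)
  mean(d)
}

#' Arc length of a cubic Bezier curve
#'
#' Integrates the speed of the cubic Bezier defined by endpoints `p0`,
#' `p1` and control points `c1`, `c2` with adaptive quadrature
#' (absolute tolerance 1e-6 mm).  Used to approximate the geodesic
#' distance between pattern points along a curved (non-flat) skin surface.
#'
#' @param p0,c1,c2,p1 numeric length-2 control points (mm).
#' @return arc length in mm.
#' @export
bezierArcLength <- function(p0, c1, c2, p1) {
  pts <- rbind(p0, c1, c2, p1)
  if (any(!is.finite(pts))) t3dError("control points must be finite", "domainError")
  speed <- function(t) {
    # derivative of the cubic Bernstein form
    dx <- 3 * (1 - t)^2 * (pts[2, 1] - pts[1, 1]) +
      6 * (1 - t) * t * (pts[3, 1] - pts[2, 1]) +
      3 * t^2 * (pts[4, 1] - pts[3, 1])
    dy <- 3 * (1 - t)^2 * (pts[2, 2] - pts[1, 2]) +
      6 * (1 - t) * t * (pts[3, 2] - pts[2, 2]) +
      3 * t^2 * (pts[4, 2] - pts[3, 2])
    sqrt(dx^2 + dy^2)
  }
  stats::integrate(speed, 0, 1, abs.tol = 1e-6,
                   subdivisions = 500L)$value
}

#' Relative increase of a geodesic distance over its Euclidean baseline
#'
#' The headline quantity of the flat-surface analysis: by how many percent
#' the along-surface (geodesic) distance between two pattern points
#' exceeds the straight-line distance assumed by the flat-pattern model.
#'
#' @param dEuclid straight-line distance (mm), > 0.
#' @param dGeodesic along-surface distance (mm), >= `dEuclid`.
#' @return relative increase in percent.
#' @examples
#' flatSurfaceDiscrepancy(17.4, 17.7)  # ~1.72%, i.e. 2% at integer rounding
#' @export
flatSurfaceDiscrepancy <- function(dEuclid, dGeodesic) {
  if (!is.finite(dEuclid) || dEuclid <= 0)
    t3dError("Euclidean distance must be positive", "domainError")
  if (dGeodesic < dEuclid)
    t3dError("geodesic distance cannot be shorter than Euclidean",
             "domainError")
  100 * (dGeodesic - dEuclid) / dEuclid
}
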