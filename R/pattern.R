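## Pose estimation from the trident fiducial.
##
## Conventions (locked by regression tests):
##   * pattern frame: right-handed; central line +z, lateral +x, depth +y;
##     the pattern lies in the plane y = 0 with apex at the origin.
##   * image frame: x lateral, y axial depth; a pixel (x, y) maps to the
##     pattern frame via Translate(0,0,a0) o RotY(alpha) o Translate(-xc,-yc,0),
##     so the image x-axis maps to (cos a, 0, -sin a).
##   * "l" is the detected peak with the smaller lateral image coordinate.
## Under this labelling the tilt estimator agrees with the geometric
## ray-line forward model with no sign flip.

t3dError <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "trident3dError")))
}

#' Construct a trident pattern specification
#'
#' The geometry may be given either as the physical pattern dimensions
#' (`dMax`, `a0Max`) or via `tanGamma` directly (in which case `dMax` is
#' derived as `2 * tanGamma * a0Max`).
#'
#' @param dMax full opening distance at the far end of the trident (mm).
#' @param a0Max vertical extent of the pattern along the central line (mm).
#' @param tanGamma half-opening slope; overrides `dMax` when given.
#' @param patternWavelength,targetWavelength acquisition wavelengths (nm).
#' @param a0GateMargin fractional tolerance past `a0Max` before a decoded
#'   pose is rejected.
#' @return a [PatternSpec-class] object.
#' @examples
#' patternSpec()                      # the 20 mm / 50 mm prototype pattern
#' patternSpec(tanGamma = 0.25, a0Max = 40)
#' @export
patternSpec <- function(dMax = 20, a0Max = 50, tanGamma = NULL,
                        patternWavelength = 750, targetWavelength = 850,
                        a0GateMargin = 0.1) {
  if (!is.null(tanGamma)) {
    dMax <- 2 * tanGamma * a0Max
  } else {
    tanGamma <- dMax / (2 * a0Max)
  }
  new("PatternSpec", tanGamma = tanGamma, dMax = dMax, a0Max = a0Max,
      patternWavelength = patternWavelength,
      targetWavelength = targetWavelength, a0GateMargin = a0GateMargin)
}

#' Construct a probe pose
#'
#' @param alpha slice tilt in radians.
#' @param a0 offset along the pattern central line (mm).
#' @param xc,yc image coordinates of the central pattern peak (mm).
#' @return a [ProbePose-class] object.
#' @export
probePose <- function(alpha, a0, xc = 0, yc = 0) {
  new("ProbePose", alpha = as.numeric(alpha), a0 = as.numeric(a0),
      xc = as.numeric(xc), yc = as.numeric(yc))
}

#' Estimate the slice pose from the two peak distances
#'
#' Inverts the trident geometry: given the in-image distances from the
#' central pattern peak to the left (`dl`) and right (`dr`) peaks, recovers
#' the slice tilt
#' \deqn{\tan\alpha = \frac{1}{\tan\gamma}\,\frac{d_l - d_r}{d_l + d_r}}
#' and the central-line offset
#' \deqn{a_0 = \frac{(d_l+d_r)\cos\alpha + (d_l-d_r)^2/(d_l+d_r)}{2\tan\gamma}.}
#'
#' @param dl,dr distances from the central peak to the left / right peak (mm).
#' @param pattern a [PatternSpec-class].
#' @param xc,yc image coordinates of the central peak, passed through (mm).
#' @param gate if `TRUE` (default) reject poses whose `a0` falls outside
#'   `(0, a0Max * (1 + a0GateMargin)]`.
#' @return a [ProbePose-class].
#' @examples
#' p <- estimatePose(4, 4, patternSpec())       # symmetric: alpha = 0, a0 = 20
#' estimatePose(4.2, 3.8, patternSpec())        # tilted slice
#' @export
estimatePose <- function(dl, dr, pattern, xc = 0, yc = 0, gate = TRUE) {
  stopifnot(is(pattern, "PatternSpec"))
  if (!is.finite(dl) || !is.finite(dr) || dl < 0 || dr < 0 || dl + dr <= 0)
    t3dError("degenerate peak distances: need dl, dr >= 0 with dl + dr > 0",
             "degenerateInputError")
  tg <- pattern@tanGamma
  alpha <- atan((1 / tg) * (dl - dr) / (dl + dr))
  a0 <- ((dl + dr) * cos(alpha) + (dl - dr)^2 / (dl + dr)) / (2 * tg)
  if (gate) {
    hi <- pattern@a0Max * (1 + pattern@a0GateMargin)
    if (a0 <= 0 || a0 > hi)
      t3dError(sprintf("decoded a0 = %.3f mm outside (0, %.3f]", a0, hi),
               "gateError")
  }
  probePose(alpha, a0, xc, yc)
}

#' Forward model: peak distances for a given pose
#'
#' Algebraic inverse of [estimatePose()]: the unique pair `(dl, dr)` that
#' the pose estimator maps back to `(alpha, a0)` exactly.
#'
#' @param pose a [ProbePose-class] (only `alpha` and `a0` are used).
#' @param pattern a [PatternSpec-class].
#' @return named numeric `c(dl =, dr =)` in mm.
#' @examples
#' intersectionDistances(probePose(0, 20), patternSpec())  # 4, 4
#' @export
intersectionDistances <- function(pose, pattern) {
  stopifnot(is(pose, "ProbePose"), is(pattern, "PatternSpec"))
  if (pose@a0 <= 0)
    t3dError("a0 must be positive for an in-pattern pose", "domainError")
  tg <- pattern@tanGamma
  ta <- tan(pose@alpha)
  S <- 2 * tg * pose@a0 / (cos(pose@alpha) + tg^2 * ta^2)
  D <- S * tg * ta
  dl <- (S + D) / 2
  dr <- (S - D) / 2
  if (dl < 0 || dr < 0)
    t3dError("pose lies outside the pattern (negative peak distance)",
             "outOfPatternError")
  c(dl = dl, dr = dr)
}

#' Exact ray-line intersection distances for a tilted slice
#'
#' The geometric forward model: the slice's intersection line with the
#' pattern plane passes through (0, 0, a0) with direction
#' (cos alpha, 0, -sin alpha); its Euclidean distances to the intersections
#' with the two tilted trident lines x = +/- tanGamma * z are returned.
#' Unlike [intersectionDistances()] (the algebraic inverse of the pose
#' estimator) this is the physically exact geometry; the difference between
#' the two is the estimator's O(sin^2 alpha) offset bias.
#'
#' @inheritParams intersectionDistances
#' @return named numeric `c(dl =, dr =)` in mm.
#' @export
rayIntersectionDistances <- function(pose, pattern) {
  stopifnot(is(pose, "ProbePose"), is(pattern, "PatternSpec"))
  if (pose@a0 <= 0)
    t3dError("a0 must be positive for an in-pattern pose", "domainError")
  tg <- pattern@tanGamma
  ca <- cos(pose@alpha); sa <- sin(pose@alpha)
  # line point P(t) = (t*ca, 0, a0 - t*sa); right line x = +tg*z, left x = -tg*z
  denR <- ca + tg * sa
  denL <- ca - tg * sa
  if (denR <= 0 || denL <= 0)
    t3dError("slice is parallel to a trident line", "outOfPatternError")
  c(dl = tg * pose@a0 / denL, dr = tg * pose@a0 / denR)
}

#' Rigid transform from image plane to pattern frame
#'
#' Composes `Translate(0, 0, a0) o RotY(alpha) o Translate(-xc, -yc, 0)`,
#' which maps the central pattern peak at image coordinates `(xc, yc, 0)`
#' exactly onto `(0, 0, a0)` on the pattern's central line.  At `alpha = 0`
#' the matrix reduces to a pure translation `(-xc, -yc, a0)` with identity
#' rotation.
#'
#' @param pose a [ProbePose-class].
#' @return a [RigidTransform-class].
#' @export
poseToTransform <- function(pose) {
  stopifnot(is(pose, "ProbePose"))
  ca <- cos(pose@alpha); sa <- sin(pose@alpha)
  R <- matrix(c(ca, 0, -sa,
                0, 1, 0,
                sa, 0, ca), 3, 3)           # column-major: RotY(alpha)
  tvec <- R %*% c(-pose@xc, -pose@yc, 0) + c(0, 0, pose@a0)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- tvec
  new("RigidTransform", matrix = m)
}

#' Build a rigid transform from a rotation and translation
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric (mm).
#' @return a [RigidTransform-class].
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  m <- diag(4)
  m[1:3, 1:3] <- rotation
  m[1:3, 4] <- translation
  new("RigidTransform", matrix = m)
}

#' Apply a rigid transform to a point cloud
#'
#' @param transform a [RigidTransform-class].
#' @param points n x 3 numeric matrix of coordinates (mm).
#' @return n x 3 matrix of transformed coordinates.
#' @export
transformPoints <- function(transform, points) {
  stopifnot(is(transform, "RigidTransform"))
  points <- asPointMatrix(points)
  if (any(!is.finite(points)))
    t3dError("point coordinates must be finite", "domainError")
  m <- transform@matrix
  out <- points %*% t(m[1:3, 1:3])
  out[, 1] <- out[, 1] + m[1, 4]
  out[, 2] <- out[, 2] + m[2, 4]
  out[, 3] <- out[, 3] + m[3, 4]
  out
}

asPointMatrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (ncol(points) != 3L) stop("points must be n x 3")
  storage.mode(points) <- "double"
  points
}

#' Pose change induced by perturbing the measured peak distances
#'
#' Exact finite difference of [estimatePose()] outputs (not a first-order
#' approximation): the pose is estimated at `(dl, dr)` and at
#' `(dl + deltaL, dr + deltaR)` and the differences are returned.  This is
#' the mechanism by which in-image distance errors (for instance from a
#' curved, non-flat pattern surface) propagate into tilt and offset errors.
#'
#' @param dl,dr unperturbed peak distances (mm).
#' @param deltaL,deltaR perturbations added to `dl` and `dr` (mm).
#' @param pattern a [PatternSpec-class].
#' @return named numeric `c(dAlpha =, dA0 =)`: tilt change in radians,
#'   offset change in mm.
#' @export
poseSensitivity <- function(dl, dr, deltaL, deltaR, pattern) {
  base <- estimatePose(dl, dr, pattern, gate = FALSE)
  pert <- estimatePose(dl + deltaL, dr + deltaR, pattern, gate = FALSE)
  c(dAlpha = pert@alpha - base@alpha, dA0 = pert@a0 - base@a0)
}
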