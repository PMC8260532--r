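## Synthetic freehand scans with ground truth.
##
## The simulator renders the pattern channel from the EXACT ray-line
## intersection of the (possibly tilted) imaging plane with the trident,
## not from the pose estimator's algebraic model, so estimator bias is
## measurable against it.

#' Build an N-wire phantom
#'
#' Layers of N-shaped wires, the standard reference object for validating
#' freehand 3D reconstruction: each layer holds two rails running along the
#' scan direction (pattern +z) plus the diagonal of the "N", all at a fixed
#' tissue depth.  Every slice therefore intersects each layer in three
#' points whose lateral positions encode the slice's z.  The wire paths are
#' densely sampled into a reference point model.
#'
#' @param layers number of N layers.
#' @param wireDiameter wire diameter (mm).
#' @param holeSpacing pitch of the mounting holes; consecutive layer depths
#'   differ by this value (mm).
#' @param layerDepths tissue depths (pattern-frame y, mm) of the layers;
#'   default `firstLayerDepth + holeSpacing * (0:(layers-1))`.
#' @param firstLayerDepth depth of the shallowest layer (mm).
#' @param width lateral extent of each N (mm; rails at x = +/- width/2).
#' @param height extent of each N along the scan direction z (mm).
#' @param zStart pattern-frame z at which the Ns begin (mm).
#' @param sampleStep spacing of the exported reference model points (mm).
#' @param intensity rendered wire intensity (arbitrary units).
#' @return a [Phantom-class]; the reference model is in
#'   `attr(, "model")` and also retrievable with [phantomModel()].
#' @examples
#' ph <- makeNWirePhantom()
#' length(ph@segments)   # 9: three strokes per layer, three layers
#' @export
makeNWirePhantom <- function(layers = 3L, wireDiameter = 0.4,
                             holeSpacing = 5, layerDepths = NULL,
                             firstLayerDepth = 8, width = 20, height = 10,
                             zStart = 15, sampleStep = 0.2, intensity = 1) {
  if (layers < 1L) t3dError("need at least one layer", "domainError")
  if (wireDiameter <= 0 || width <= 0 || height <= 0 || sampleStep <= 0)
    t3dError("phantom dimensions must be positive", "domainError")
  if (is.null(layerDepths))
    layerDepths <- firstLayerDepth + holeSpacing * (seq_len(layers) - 1)
  if (length(layerDepths) != layers)
    t3dError("'layerDepths' must have one entry per layer", "domainError")
  hw <- width / 2
  segs <- list()
  for (d in layerDepths) {
    segs <- c(segs, list(
      list(from = c(-hw, d, zStart), to = c(-hw, d, zStart + height),
           diameter = wireDiameter, intensity = intensity),
      list(from = c(-hw, d, zStart), to = c(hw, d, zStart + height),
           diameter = wireDiameter, intensity = intensity),
      list(from = c(hw, d, zStart), to = c(hw, d, zStart + height),
           diameter = wireDiameter, intensity = intensity)))
  }
  ph <- newPhantom(segments = segs)
  attr(ph, "model") <- samplePhantomModel(ph, sampleStep)
  ph
}

#' Build a vessel phantom
#'
#' A single tube following a centreline polyline, emulating a forearm
#' vessel target.
#'
#' @param centerline n x 3 matrix of centreline points (pattern frame, mm).
#' @param radius tube radius (mm).
#' @param sampleStep spacing of exported centreline truth points (mm).
#' @param intensity rendered intensity.
#' @return a [Phantom-class] whose reference model is the densely resampled
#'   centreline.
#' @export
makeVesselPhantom <- function(centerline, radius = 1, sampleStep = 0.2,
                              intensity = 1) {
  centerline <- asPointMatrix(centerline)
  if (nrow(centerline) < 2L)
    t3dError("centreline needs at least 2 points", "domainError")
  if (radius <= 0) t3dError("radius must be positive", "domainError")
  ph <- newPhantom(tubes = list(list(centerline = centerline,
                                     radius = radius,
                                     intensity = intensity)))
  attr(ph, "model") <- resamplePolyline(centerline, sampleStep)
  ph
}

newPhantom <- function(segments = list(), tubes = list()) {
  pts <- rbind(
    do.call(rbind, lapply(segments, function(s) rbind(s$from, s$to))),
    do.call(rbind, lapply(tubes, function(tb) tb$centerline)))
  bb <- rbind(apply(pts, 2, min), apply(pts, 2, max))
  new("Phantom", segments = segments, tubes = tubes, boundingBox = bb)
}

#' Reference point model of a phantom
#'
#' @param phantom a [Phantom-class] built by [makeNWirePhantom()] or
#'   [makeVesselPhantom()].
#' @param sampleStep resampling step if the model must be rebuilt (mm).
#' @return n x 3 matrix of model points (mm).
#' @export
phantomModel <- function(phantom, sampleStep = 0.2) {
  m <- attr(phantom, "model")
  if (!is.null(m)) return(m)
  samplePhantomModel(phantom, sampleStep)
}

samplePhantomModel <- function(phantom, step) {
  pts <- lapply(phantom@segments, function(s)
    resamplePolyline(rbind(s$from, s$to), step))
  pts <- c(pts, lapply(phantom@tubes, function(tb)
    resamplePolyline(tb$centerline, step)))
  do.call(rbind, pts)
}

resamplePolyline <- function(poly, step) {
  out <- list()
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(1L, ceiling(len / step))
    t <- seq(0, 1, length.out = n + 1L)
    seg <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
                 a[3] + t * (b[3] - a[3]))
    if (i > 1L) seg <- seg[-1L, , drop = FALSE]  # avoid duplicated joints
    out[[i]] <- seg
  }
  unname(do.call(rbind, out))
}

#' Freehand trajectory configuration
#'
#' @param mode `"careful"` (slow monotone sweep) or `"careless"` (fast
#'   random walk with direction changes).
#' @param nSlices number of slices.
#' @param a0Range numeric length 2: sweep range of the central-line offset
#'   (mm).
#' @param alphaJitterSd standard deviation of the per-slice tilt jitter
#'   (degrees).
#' @param tiltSd standard deviation of the out-of-plane tilt, i.e. the
#'   orthogonality-constraint violation (degrees).
#' @param flipProb per-step probability of a direction change (careless
#'   mode only).
#' @param seed integer random seed.
#' @return a validated list of class `"TrajectoryConfig"`.
#' @export
trajectoryConfig <- function(mode = c("careful", "careless"), nSlices = 60L,
                             a0Range = c(12, 38), alphaJitterSd = 0,
                             tiltSd = 0, flipProb = 0.2, seed = 1L) {
  mode <- match.arg(mode)
  if (nSlices < 1L) t3dError("'nSlices' must be >= 1", "configError")
  if (alphaJitterSd < 0 || tiltSd < 0)
    t3dError("jitter SDs must be non-negative", "configError")
  if (flipProb < 0 || flipProb > 1)
    t3dError("'flipProb' must be in [0, 1]", "configError")
  structure(list(mode = mode, nSlices = as.integer(nSlices),
                 a0Range = sort(as.numeric(a0Range)),
                 alphaJitterSd = alphaJitterSd, tiltSd = tiltSd,
                 flipProb = flipProb, seed = as.integer(seed)),
            class = "TrajectoryConfig")
}

#' Sample a freehand probe trajectory
#'
#' Careful mode sweeps `a0` linearly across the range with Gaussian tilt
#' jitter; careless mode performs a random walk in `a0` with the careful
#' step size, flipping direction with probability `flipProb` each step and
#' reflecting at the range ends.  Fully determined by the seed.
#'
#' @param config a [trajectoryConfig()].
#' @return data.frame with columns `index`, `alpha` (rad), `a0` (mm),
#'   `xc`, `yc` (mm), `tilt` (rad).
#' @export
sampleTrajectory <- function(config) {
  stopifnot(inherits(config, "TrajectoryConfig"))
  n <- config$nSlices
  lo <- config$a0Range[1]; hi <- config$a0Range[2]
  a0 <- numeric(n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(config$seed)
  if (config$mode == "careful") {
    a0 <- if (n == 1L) (lo + hi) / 2 else seq(lo, hi, length.out = n)
  } else {
    step <- if (n == 1L) 0 else (hi - lo) / (n - 1)
    pos <- lo
    dir <- 1
    for (i in seq_len(n)) {
      a0[i] <- pos
      if (stats::runif(1) < config$flipProb) dir <- -dir
      pos <- pos + dir * step
      if (pos > hi) { pos <- hi - (pos - hi); dir <- -dir }
      if (pos < lo) { pos <- lo + (lo - pos); dir <- -dir }
    }
  }
  alpha <- stats::rnorm(n, 0, config$alphaJitterSd) * pi / 180
  tilt <- stats::rnorm(n, 0, config$tiltSd) * pi / 180
  data.frame(index = seq_len(n), alpha = alpha, a0 = a0,
             xc = rep(NA_real_, n), yc = rep(NA_real_, n), tilt = tilt)
}

#' Image geometry for rendered slices
#'
#' @param width lateral field of view (mm).
#' @param depth axial field of view (mm).
#' @param pixelSpacing pixel size, lateral and axial (mm).
#' @param surfaceDepth axial image depth of the skin/pattern surface (mm);
#'   the truth `yc` of every rendered slice.
#' @return list of class `"ImageGeometry"`.
#' @export
imageGeometry <- function(width = 40, depth = 30,
                          pixelSpacing = c(0.2, 0.2), surfaceDepth = 4) {
  structure(list(width = width, depth = depth,
                 pixelSpacing = stats::setNames(as.numeric(pixelSpacing),
                                                c("lateral", "axial")),
                 surfaceDepth = surfaceDepth),
            class = "ImageGeometry")
}

#' Noise model for rendered slices
#'
#' @param blobSigma Gaussian footprint of the pattern peaks (mm).
#' @param blobJitterSd positional jitter of each pattern peak (mm).
#' @param pixelNoiseSd additive white pixel noise, as a fraction of the
#'   peak amplitude.
#' @param spuriousRate expected number of spurious bright blobs per slice
#'   (Poisson).
#' @return list of class `"NoiseModel"`.
#' @export
noiseModel <- function(blobSigma = 0.3, blobJitterSd = 0, pixelNoiseSd = 0,
                       spuriousRate = 0) {
  structure(list(blobSigma = blobSigma, blobJitterSd = blobJitterSd,
                 pixelNoiseSd = pixelNoiseSd, spuriousRate = spuriousRate),
            class = "NoiseModel")
}

## Gaussian blob splat, vectorised over pixels.
addBlob <- function(img, x0, y0, sigma, amp, dx, dy) {
  xs <- (seq_len(ncol(img)) - 1) * dx
  ys <- (seq_len(nrow(img)) - 1) * dy
  gx <- exp(-(xs - x0)^2 / (2 * sigma^2))
  gy <- exp(-(ys - y0)^2 / (2 * sigma^2))
  img + amp * outer(gy, gx)
}

#' Render one synthetic slice
#'
#' The pattern channel holds Gaussian blobs at the exact 3D intersections
#' of the (possibly tilted) imaging plane with the three trident lines,
#' mapped into image coordinates; the target channel holds intensity where
#' the plane cuts phantom primitives.  A nonzero out-of-plane tilt leaves
#' the pattern intersections unchanged (the tilt axis is the surface
#' intersection line itself) but skews where deep structures are sampled —
#' the physically correct consequence of violating the orthogonality
#' constraint.
#'
#' @param phantom a [Phantom-class] or `NULL` for no target content.
#' @param pose a [ProbePose-class]; its `xc`, `yc` place the pattern in the
#'   image (use [imageGeometry()]'s surface depth for `yc`).
#' @param pattern a [PatternSpec-class].
#' @param geom an [imageGeometry()].
#' @param noise a [noiseModel()].
#' @param tilt out-of-plane tilt in radians.
#' @param index acquisition index stored in the slice.
#' @param seed optional integer seed for this slice's noise draws.
#' @return a [PASlice-class].
#' @export
renderSlice <- function(phantom, pose, pattern, geom = imageGeometry(),
                        noise = noiseModel(), tilt = 0, index = 1L,
                        seed = NULL) {
  stopifnot(is(pose, "ProbePose"), is(pattern, "PatternSpec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  dx <- geom$pixelSpacing[["lateral"]]; dy <- geom$pixelSpacing[["axial"]]
  ncolp <- round(geom$width / dx) + 1L
  nrowp <- round(geom$depth / dy) + 1L
  pat <- matrix(0, nrowp, ncolp)
  tgt <- matrix(0, nrowp, ncolp)
  tg <- pattern@tanGamma
  ca <- cos(pose@alpha); sa <- sin(pose@alpha)
  amp <- 1

  # pattern channel: exact ray-line intersections, z gated to the extent
  if (pose@a0 > 0 && pose@a0 <= pattern@a0Max) {
    denL <- ca - tg * sa; denR <- ca + tg * sa
    ts <- c(l = if (denL > 0) -tg * pose@a0 / denL else NA_real_,
            c = 0,
            r = if (denR > 0) tg * pose@a0 / denR else NA_real_)
    for (t in ts) {
      if (is.na(t)) next
      zInt <- pose@a0 - t * sa            # pattern-frame z of intersection
      if (zInt < 0 || zInt > pattern@a0Max) next
      x0 <- pose@xc + t
      y0 <- pose@yc
      if (noise$blobJitterSd > 0) {
        x0 <- x0 + stats::rnorm(1, 0, noise$blobJitterSd)
        y0 <- y0 + stats::rnorm(1, 0, noise$blobJitterSd)
      }
      if (x0 >= 0 && x0 <= geom$width)
        pat <- addBlob(pat, x0, y0, noise$blobSigma, amp, dx, dy)
    }
  }
  if (noise$spuriousRate > 0) {
    k <- stats::rpois(1, noise$spuriousRate)
    for (i in seq_len(k))
      pat <- addBlob(pat, stats::runif(1, 0, geom$width),
                     stats::runif(1, 0, geom$depth),
                     noise$blobSigma, amp * stats::runif(1, 0.5, 1), dx, dy)
  }

  # target channel: map every pixel into the pattern frame along the
  # (possibly tilted) plane basis and test against phantom primitives
  if (!is.null(phantom)) {
    e1 <- c(ca, 0, -sa)
    nrm <- c(sa, 0, ca)                       # e1 x yhat
    e2 <- cos(tilt) * c(0, 1, 0) + sin(tilt) * nrm
    pc <- c(0, 0, pose@a0)
    xs <- (seq_len(ncolp) - 1) * dx - pose@xc
    ys <- (seq_len(nrowp) - 1) * dy - pose@yc
    u <- rep(xs, each = nrowp)
    v <- rep(ys, times = ncolp)
    px <- pc[1] + u * e1[1] + v * e2[1]
    py <- pc[2] + u * e1[2] + v * e2[2]
    pz <- pc[3] + u * e1[3] + v * e2[3]
    val <- numeric(length(px))
    for (s in phantom@segments) {
      d2 <- pointSegmentDist2(px, py, pz, s$from, s$to)
      val <- pmax(val, ifelse(d2 <= (s$diameter / 2)^2, s$intensity, 0))
    }
    for (tb in phantom@tubes) {
      d2 <- rep(Inf, length(px))
      cl <- tb$centerline
      for (i in seq_len(nrow(cl) - 1L))
        d2 <- pmin(d2, pointSegmentDist2(px, py, pz, cl[i, ], cl[i + 1L, ]))
      val <- pmax(val, ifelse(d2 <= tb$radius^2, tb$intensity, 0))
    }
    tgt <- matrix(val, nrowp, ncolp)
  }

  if (noise$pixelNoiseSd > 0) {
    pat <- pat + matrix(stats::rnorm(length(pat), 0, noise$pixelNoiseSd * amp),
                        nrowp, ncolp)
    tgt <- tgt + matrix(stats::rnorm(length(tgt), 0, noise$pixelNoiseSd * amp),
                        nrowp, ncolp)
  }
  paSlice(pat, tgt, geom$pixelSpacing, index)
}

## squared distance from points (x,y,z) to segment a--b, vectorised
pointSegmentDist2 <- function(x, y, z, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- ((x - a[1]) * ab[1] + (y - a[2]) * ab[2] + (z - a[3]) * ab[3]) / len2
  t <- pmin(1, pmax(0, t))
  (x - (a[1] + t * ab[1]))^2 + (y - (a[2] + t * ab[2]))^2 +
    (z - (a[3] + t * ab[3]))^2
}

#' Simulate a complete freehand scan
#'
#' Samples a trajectory, renders every slice, and bundles the stack with
#' its ground-truth poses and the phantom reference model.
#'
#' @param phantom a [Phantom-class].
#' @param trajectory a [trajectoryConfig()].
#' @param pattern a [PatternSpec-class].
#' @param geom an [imageGeometry()].
#' @param noise a [noiseModel()].
#' @return a [SyntheticScan-class].
#' @export
simulateScan <- function(phantom, trajectory = trajectoryConfig(),
                         pattern = patternSpec(), geom = imageGeometry(),
                         noise = noiseModel()) {
  poses <- sampleTrajectory(trajectory)
  poses$xc <- geom$width / 2
  poses$yc <- geom$surfaceDepth
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(trajectory$seed)
  sliceSeeds <- sample.int(.Machine$integer.max - 1L, nrow(poses))
  slices <- lapply(seq_len(nrow(poses)), function(i) {
    renderSlice(phantom, probePose(poses$alpha[i], poses$a0[i],
                                   poses$xc[i], poses$yc[i]),
                pattern, geom, noise, tilt = poses$tilt[i], index = i,
                seed = sliceSeeds[i])
  })
  new("SyntheticScan", slices = slices, truthPoses = poses,
      truthModel = phantomModel(phantom),
      config = list(trajectory = unclass(trajectory),
                    geometry = unclass(geom), noise = unclass(noise),
                    pattern = list(dMax = pattern@dMax,
                                   a0Max = pattern@a0Max,
                                   tanGamma = pattern@tanGamma)))
}
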