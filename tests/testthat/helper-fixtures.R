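# Shared fixture builders for the test suite.  Everything is generated in
# code; no binary fixtures.

# the prototype pattern: 20 mm opening over 50 mm extent, tan(gamma) = 0.2
protoPattern <- function(...) patternSpec(dMax = 20, a0Max = 50, ...)

# a slice whose pattern channel holds ideal Gaussian blobs at given
# lateral positions (mm) on a given surface row
blobSlice <- function(lateral, surfaceDepth = 4, width = 40, depth = 30,
                      spacing = 0.1, sigma = 0.3, amp = 1, index = 1L) {
  nc <- round(width / spacing) + 1L
  nr <- round(depth / spacing) + 1L
  img <- matrix(0, nr, nc)
  xs <- (seq_len(nc) - 1) * spacing
  ys <- (seq_len(nr) - 1) * spacing
  for (x0 in lateral)
    img <- img + amp * outer(exp(-(ys - surfaceDepth)^2 / (2 * sigma^2)),
                             exp(-(xs - x0)^2 / (2 * sigma^2)))
  paSlice(img, img * 0, c(spacing, spacing), index)
}

# small random slice set + rigid transforms for compounding properties
randomSliceSet <- function(nSlices = 3L, nr = 6L, nc = 7L, spacing = 0.5) {
  slices <- lapply(seq_len(nSlices), function(i)
    paSlice(matrix(0, nr, nc),
            matrix(runif(nr * nc), nr, nc),
            c(spacing, spacing), i))
  transforms <- lapply(seq_len(nSlices), function(i) {
    a <- runif(1, -0.3, 0.3)
    poseToTransform(probePose(a, runif(1, 5, 20),
                              runif(1, 0, 2), runif(1, 0, 2)))
  })
  list(slices = slices, transforms = transforms)
}

# dense wire-frame cloud for ICP tests; irregular arclength sampling, as a
# regular grid would alias translations along the rails
wireCloud <- function(step = 0.4, seed = 10) {
  set.seed(seed)
  ph <- makeNWirePhantom()
  do.call(rbind, lapply(ph@segments, function(s) {
    len <- sqrt(sum((s$to - s$from)^2))
    t <- sort(runif(ceiling(len / step)))
    outer(rep(1, length(t)), s$from) + outer(t, s$to - s$from)
  }))
}

rotYdeg <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

# reference phantom reconstruction used by the end-to-end checks
reconstructPhantomScan <- function(noise = noiseModel(), seed = 7L,
                                   nSlices = 60L) {
  ph <- makeNWirePhantom()
  scan <- simulateScan(ph, trajectoryConfig("careful", nSlices, c(12, 38),
                                            seed = seed), noise = noise)
  poses <- stackPoses(scanSlices(scan), protoPattern())
  acc <- which(poses$accepted)
  trs <- lapply(acc, function(i)
    poseToTransform(probePose(poses$alpha_deg[i] * pi / 180,
                              poses$a0_mm[i], poses$x_c_mm[i],
                              poses$y_c_mm[i])))
  vol <- compoundVolume(scanSlices(scan)[acc], trs)
  cloud <- thresholdSegment(vol, 0.5, relative = TRUE)
  list(scan = scan, poses = poses, volume = vol, cloud = cloud,
       model = phantomModel(ph))
}

# Gaussian-cross-section vessel volume with the centre at (cx, cy) in
# every z plane; used by the MVD checks
vesselVolume <- function(cx, cy, nx = 41L, ny = 41L, nz = 8L,
                         spacing = 0.5, sigma = 1.0) {
  xs <- (seq_len(nx) - 1) * spacing
  ys <- (seq_len(ny) - 1) * spacing
  plane <- outer(exp(-(xs - cx)^2 / (2 * sigma^2)),
                 exp(-(ys - cy)^2 / (2 * sigma^2)))
  vals <- array(rep(plane, nz), dim = c(nx, ny, nz))
  new("VoxelVolume", origin = c(0, 0, 0),
      spacing = rep(spacing, 3), values = vals,
      counts = array(1L, dim = dim(vals)))
}
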