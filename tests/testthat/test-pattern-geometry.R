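# Trident geometry: pose estimator, its algebraic inverse, rigid
# transforms and the sensitivity of the pose to distance perturbations.

test_that("pattern spec validates its geometry", {
  p <- protoPattern()
  expect_equal(p@tanGamma, 0.2)
  expect_equal(patternSpec(tanGamma = 0.25, a0Max = 40)@dMax, 20)
  expect_error(patternSpec(dMax = -1), "positive")
  expect_error(patternSpec(patternWavelength = 850, targetWavelength = 850),
               "distinct")
})

test_that("pose estimation matches hand-evaluated closed forms", {
  p <- protoPattern()
  # symmetric case: alpha forced to zero, a0 = (dl+dr)/(2 tan gamma)
  sym <- estimatePose(4, 4, p)
  expect_equal(sym@alpha, 0)
  expect_equal(sym@a0, 20)
  # oracle: tan(alpha) = 5*(0.4/8); a0 = (8*cos(alpha) + 0.16/8)/0.4
  a1 <- atan(5 * (4.2 - 3.8) / 8)
  e1 <- estimatePose(4.2, 3.8, p)
  expect_equal(e1@alpha, a1, tolerance = 1e-12)
  expect_equal(e1@a0, (8 * cos(a1) + 0.4^2 / 8) / 0.4, tolerance = 1e-12)
  expect_equal(e1@alpha * 180 / pi, 14.036, tolerance = 1e-3)
  expect_equal(e1@a0, 19.453, tolerance = 1e-3)
  # strongly tilted: tan(alpha) = 1.25
  a2 <- atan(1.25)
  e2 <- estimatePose(5, 3, p)
  expect_equal(e2@alpha, a2, tolerance = 1e-12)
  expect_equal(e2@a0, (8 * cos(a2) + 4 / 8) / 0.4, tolerance = 1e-12)
  expect_equal(e2@alpha * 180 / pi, 51.340, tolerance = 1e-3)
  expect_equal(e2@a0, 13.744, tolerance = 1e-3)
})

test_that("degenerate and gated inputs are rejected", {
  p <- protoPattern()
  expect_error(estimatePose(0, 0, p), class = "degenerateInputError")
  expect_error(estimatePose(-1, 2, p), class = "degenerateInputError")
  # a0 past the gate: dl = dr = 12 gives a0 = 60 > 55
  expect_error(estimatePose(12, 12, p), class = "gateError")
  expect_s4_class(estimatePose(12, 12, p, gate = FALSE), "ProbePose")
  expect_error(intersectionDistances(probePose(0, 0), p),
               class = "domainError")
  expect_error(intersectionDistances(probePose(0, -3), p),
               class = "domainError")
})

test_that("intersection distances invert the estimator over a pose grid", {
  p <- protoPattern()
  sym <- intersectionDistances(probePose(0, 20), p)
  expect_equal(unname(sym), c(4, 4))
  d <- intersectionDistances(probePose(atan(0.25), 19.4528), p)
  expect_equal(unname(d), c(4.2, 3.8), tolerance = 1e-3)
  grid <- expand.grid(alpha = seq(-45, 45, length.out = 9) * pi / 180,
                      a0 = seq(1, 50, length.out = 9))
  for (i in seq_len(nrow(grid))) {
    dd <- intersectionDistances(probePose(grid$alpha[i], grid$a0[i]), p)
    est <- estimatePose(dd["dl"], dd["dr"], p, gate = FALSE)
    expect_equal(est@alpha, grid$alpha[i], tolerance = 1e-9)
    expect_equal(est@a0, grid$a0[i], tolerance = 1e-9)
  }
})

test_that("swapping dl and dr negates the tilt and keeps the offset", {
  p <- protoPattern()
  for (dd in list(c(4.2, 3.8), c(5, 3), c(2.2, 6.1))) {
    e1 <- estimatePose(dd[1], dd[2], p, gate = FALSE)
    e2 <- estimatePose(dd[2], dd[1], p, gate = FALSE)
    expect_equal(e1@alpha, -e2@alpha)
    expect_equal(e1@a0, e2@a0)
  }
})

test_that("pose transform composes translation-after-rotation correctly", {
  # identity at the origin pose
  expect_equal(transformMatrix(poseToTransform(probePose(0, 0))), diag(4))
  # at alpha = 0 the matrix is a pure translation (-xc, -yc, a0)
  m <- transformMatrix(poseToTransform(probePose(0, 30, xc = 2, yc = 1)))
  expect_equal(m[1:3, 1:3], diag(3))
  expect_equal(m[1:3, 4], c(-2, -1, 30))
  # the central peak maps exactly onto (0, 0, a0) for any tilt
  tr <- poseToTransform(probePose(10 * pi / 180, 25, xc = 3, yc = 2))
  expect_equal(as.vector(transformPoints(tr, c(3, 2, 0))), c(0, 0, 25),
               tolerance = 1e-12)
})

test_that("rotation blocks are orthonormal with determinant +1", {
  set.seed(42)
  for (i in 1:25) {
    tr <- poseToTransform(probePose(runif(1, -1.2, 1.2), runif(1, 1, 50),
                                    runif(1, -5, 5), runif(1, -5, 5)))
    R <- transformMatrix(tr)[1:3, 1:3]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("axis convention: RotY(90 deg) maps +x to -z", {
  tr <- rigidTransform(rotYdeg(90))
  expect_equal(as.vector(transformPoints(tr, c(1, 0, 0))), c(0, 0, -1),
               tolerance = 1e-12)
  # pure translation
  tr2 <- rigidTransform(translation = c(1, 2, 3))
  expect_equal(as.vector(transformPoints(tr2, c(0, 0, 0))), c(1, 2, 3))
})

test_that("transforms preserve pairwise distances", {
  set.seed(7)
  pts <- matrix(rnorm(30), 10, 3)
  tr <- poseToTransform(probePose(0.4, 17, 1.5, 2.5))
  out <- transformPoints(tr, pts)
  expect_equal(dim(out), dim(pts))
  expect_lt(max(abs(dist(out) - dist(pts))), 1e-9)
  expect_error(transformPoints(tr, matrix(c(1, NA, 3), 1)),
               class = "domainError")
})

test_that("pose sensitivity is the exact finite difference of the estimator", {
  p <- protoPattern()
  expect_equal(unname(poseSensitivity(4, 4, 0, 0, p)), c(0, 0))
  # oracle: two evaluations of the closed forms
  s <- poseSensitivity(4, 4, 0.1, 0, p)
  a1 <- atan(5 * 0.1 / 8.1)
  expect_equal(unname(s["dAlpha"]) * 180 / pi, 3.533, tolerance = 1e-3)
  expect_equal(unname(s["dA0"]),
               (8.1 * cos(a1) + 0.01 / 8.1) / 0.4 - 20, tolerance = 1e-12)
  expect_equal(round(unname(s["dA0"]), 3), 0.215)
  # uniform scaling leaves the tilt unchanged exactly
  s2 <- poseSensitivity(4, 4, 0.04 * 4, 0.04 * 4, p)
  expect_equal(unname(s2["dAlpha"]), 0)
})

test_that("ray-geometry distances expose the estimator's offset bias", {
  p <- protoPattern()
  # straight pose: ray model and algebraic inverse coincide
  expect_equal(rayIntersectionDistances(probePose(0, 20), p),
               intersectionDistances(probePose(0, 20), p))
  # tilted: the tilt is recovered exactly, the offset with a small bias
  grid <- expand.grid(alpha = seq(-10, 10, length.out = 11) * pi / 180,
                      a0 = seq(5, 50, length.out = 10))
  biases <- mapply(function(al, a0) {
    d <- rayIntersectionDistances(probePose(al, a0), p)
    e <- estimatePose(d["dl"], d["dr"], p, gate = FALSE)
    c(alphaErr = abs(e@alpha - al), a0Bias = abs(e@a0 - a0))
  }, grid$alpha, grid$a0)
  expect_lt(max(biases["alphaErr", ]) * 180 / pi, 1e-9)
  expect_lt(max(biases["a0Bias", ]), 0.2)
  # bias grows with tilt (O(sin^2 alpha)): compare 2 vs 10 degrees
  biasAt <- function(deg) {
    d <- rayIntersectionDistances(probePose(deg * pi / 180, 50), p)
    abs(estimatePose(d["dl"], d["dr"], p, gate = FALSE)@a0 - 50)
  }
  expect_gt(biasAt(10), biasAt(2))
})
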