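# Synthetic scan generation: phantoms, trajectories, slice rendering.

test_that("N-wire phantom has three strokes per layer and a dense model", {
  ph <- makeNWirePhantom()
  expect_equal(length(ph@segments), 9L)
  expect_equal(length(makeNWirePhantom(layers = 1L)@segments), 3L)
  # consecutive layer depths honour the hole pitch
  depths <- sort(unique(vapply(ph@segments, function(s) s$from[2],
                               numeric(1))))
  expect_equal(diff(depths), c(5, 5))
  # a 10 mm segment sampled at 0.2 mm steps has 51 points
  seg <- trident3d:::resamplePolyline(rbind(c(0, 0, 0), c(0, 0, 10)), 0.2)
  expect_equal(nrow(seg), 51L)
  expect_error(makeNWirePhantom(wireDiameter = 0), class = "domainError")
})

test_that("vessel phantom slices to a disc and validates inputs", {
  cl <- cbind(5, 10, seq(0, 40, by = 2))
  ph <- makeVesselPhantom(cl, radius = 1)
  expect_equal(length(ph@tubes), 1L)
  s <- renderSlice(ph, probePose(0, 20, 20, 4), protoPattern(),
                   imageGeometry(pixelSpacing = c(0.2, 0.2)))
  tgt <- targetChannel(s)
  hit <- which(tgt > 0, arr.ind = TRUE)
  # pattern x=5 appears at image x = xc + 5 = 25 mm; depth y = yc + 10 = 14
  expect_equal(mean((hit[, 2] - 1) * 0.2), 25, tolerance = 0.2)
  expect_equal(mean((hit[, 1] - 1) * 0.2), 14, tolerance = 0.2)
  # sinusoidal centreline: per-slice centre follows the analytic curve
  zz <- seq(0, 40, by = 0.5)
  sin_cl <- cbind(5 + 3 * sin(2 * pi * zz / 40), 10, zz)
  ph2 <- makeVesselPhantom(sin_cl, radius = 1)
  s2 <- renderSlice(ph2, probePose(0, 30, 20, 4), protoPattern(),
                    imageGeometry(pixelSpacing = c(0.2, 0.2)))
  hit2 <- which(targetChannel(s2) > 0, arr.ind = TRUE)
  expect_equal(mean((hit2[, 2] - 1) * 0.2) - 20, 5 + 3 * sin(2 * pi * 30 / 40),
               tolerance = 0.3)
  expect_error(makeVesselPhantom(cl, radius = 0), class = "domainError")
  expect_error(makeVesselPhantom(cl[1, , drop = FALSE]),
               class = "domainError")
})

test_that("careful trajectories sweep linearly and reproducibly", {
  cfg <- trajectoryConfig("careful", 5, c(10, 30), seed = 3)
  tr <- sampleTrajectory(cfg)
  expect_equal(tr$a0, c(10, 15, 20, 25, 30))
  expect_equal(tr$alpha, rep(0, 5))
  expect_identical(tr, sampleTrajectory(cfg))
})

test_that("careless trajectories alternate direction at flip probability 1", {
  cfg <- trajectoryConfig("careless", 8, c(10, 30), flipProb = 1, seed = 5)
  tr <- sampleTrajectory(cfg)
  incs <- diff(tr$a0)
  expect_true(all(abs(incs) == abs(incs[1])))
  expect_true(all(sign(incs[-1]) == -sign(incs[-length(incs)])))
})

test_that("rendered pattern blobs sit at the exact ray intersections", {
  p <- protoPattern()
  s <- renderSlice(NULL, probePose(0, 20, 20, 4), p,
                   imageGeometry(pixelSpacing = c(0.1, 0.1)))
  pk <- detectPeaks(depthProfile(s), minSeparation = 1)
  expect_equal(nrow(pk), 3L)
  expect_equal(diff(pk$lateral), c(4, 4), tolerance = 1e-3)
  # out-of-pattern pose renders an empty pattern channel
  s2 <- renderSlice(NULL, probePose(0, 58, 20, 4), p, imageGeometry())
  expect_true(all(patternChannel(s2) == 0))
})

test_that("rendering is bit-identical for a fixed seed", {
  ph <- makeNWirePhantom()
  p <- protoPattern()
  args <- list(ph, probePose(0.05, 20, 20, 4), p, imageGeometry(),
               noiseModel(blobJitterSd = 0.1, pixelNoiseSd = 0.05,
                          spuriousRate = 1))
  s1 <- do.call(renderSlice, c(args, seed = 99L))
  s2 <- do.call(renderSlice, c(args, seed = 99L))
  expect_identical(patternChannel(s1), patternChannel(s2))
  expect_identical(targetChannel(s1), targetChannel(s2))
  s3 <- do.call(renderSlice, c(args, seed = 100L))
  expect_false(identical(patternChannel(s1), patternChannel(s3)))
})

test_that("simulated scans are reproducible end to end", {
  ph <- makeNWirePhantom()
  cfg <- trajectoryConfig("careful", 4, c(15, 25), alphaJitterSd = 1,
                          seed = 21)
  sc1 <- simulateScan(ph, cfg, noise = noiseModel(pixelNoiseSd = 0.02))
  sc2 <- simulateScan(ph, cfg, noise = noiseModel(pixelNoiseSd = 0.02))
  expect_identical(truthPoses(sc1), truthPoses(sc2))
  expect_identical(patternChannel(scanSlices(sc1)[[3]]),
                   patternChannel(scanSlices(sc2)[[3]]))
})

test_that("decoding recovers noiseless rendered poses over a tilt/offset grid", {
  p <- protoPattern()
  geom <- imageGeometry(pixelSpacing = c(0.1, 0.1))
  grid <- expand.grid(alphaDeg = seq(-10, 10, length.out = 5),
                      a0 = seq(8, 45, length.out = 5))
  for (i in seq_len(nrow(grid))) {
    s <- renderSlice(NULL, probePose(grid$alphaDeg[i] * pi / 180,
                                     grid$a0[i], 20, 4), p, geom)
    r <- slicePose(s, p)
    expect_true(r$accepted)
    expect_lt(abs(r$pose@alpha * 180 / pi - grid$alphaDeg[i]), 0.05)
    expect_lt(abs(r$pose@a0 - grid$a0[i]), 0.2)
  }
})

test_that("offset error grows monotonically with blob jitter", {
  p <- protoPattern()
  geom <- imageGeometry(pixelSpacing = c(0.2, 0.2))
  medianErr <- function(sd, seed) {
    set.seed(seed)
    errs <- replicate(60, {
      s <- renderSlice(NULL, probePose(0, 25, 20, 4), p, geom,
                       noiseModel(blobJitterSd = sd),
                       seed = sample.int(1e6, 1))
      r <- slicePose(s, p)
      if (r$accepted) abs(r$pose@a0 - 25) else NA_real_
    })
    median(errs, na.rm = TRUE)
  }
  e <- c(medianErr(0, 31), medianErr(0.1, 32), medianErr(0.4, 33))
  expect_true(all(diff(e) >= 0))
})
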