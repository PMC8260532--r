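# Peak extraction from the pattern channel and per-slice pose decoding.

test_that("depth profile takes the banded per-column maximum", {
  img <- matrix(0, 30, 40)
  img[10, 20] <- 5
  s <- paSlice(img, img * 0, c(0.1, 0.1))
  prof <- depthProfile(s)
  expect_equal(which.max(prof$profile), 20)
  expect_equal(prof$depth[20], 9 * 0.1)
  # uniform zero image -> all-zero profile
  z <- depthProfile(paSlice(matrix(0, 10, 10), pixelSpacing = c(0.1, 0.1)))
  expect_true(all(z$profile == 0))
  # band excluding the blob removes it from the profile; brute-force oracle
  img2 <- matrix(0, 50, 30)
  img2[10, 5] <- 1   # depth 0.9 mm
  img2[40, 25] <- 2  # depth 3.9 mm
  s2 <- paSlice(img2, img2 * 0, c(0.1, 0.1))
  banded <- depthProfile(s2, depthBand = c(0, 2))
  oracle <- apply(img2[1:21, ], 2, max)
  expect_equal(banded$profile, oracle)
  expect_equal(max(banded$profile), 1)
  expect_error(depthProfile(s2, depthBand = c(20, 30)), class = "domainError")
})

test_that("peak detection finds isolated, plateau and sub-pixel peaks", {
  # three delta peaks at 10, 14, 18 mm on a 0.1 mm grid
  v <- numeric(301)
  v[c(101, 141, 181)] <- 1
  pk <- detectPeaks(v, minProminence = 0.5, spacing = 0.1)
  expect_equal(pk$lateral, c(10, 14, 18))
  # flat profile -> empty
  expect_equal(nrow(detectPeaks(rep(1, 50), spacing = 0.1)), 0L)
  # analytic Gaussian: detected position within 0.02 mm of the dense-grid
  # argmax (which is the true centre)
  xs <- seq(0, 24, by = 0.1)
  g <- exp(-(xs - 12.05)^2 / (2 * 0.3^2))
  fine <- seq(0, 24, by = 1e-4)
  oracle <- fine[which.max(exp(-(fine - 12.05)^2 / (2 * 0.3^2)))]
  pkg <- detectPeaks(g, minProminence = 0.3, spacing = 0.1)
  expect_equal(nrow(pkg), 1L)
  expect_lt(abs(pkg$lateral - oracle), 0.02)
  # plateau: midpoint is returned
  vp <- c(0, 0, 1, 1, 1, 0, 0)
  expect_equal(detectPeaks(vp, minProminence = 0.5, spacing = 1)$lateral, 3)
})

test_that("separation filter keeps the more prominent of close peaks", {
  v <- numeric(100)
  v[40] <- 1
  v[44] <- 0.6   # 0.4 mm away at 0.1 mm spacing
  pk <- detectPeaks(v, minProminence = 0.1, minSeparation = 1, spacing = 0.1)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$lateral, 3.9)
})

test_that("triplet selection enumerates and gates candidate triplets", {
  p <- protoPattern()
  cand3 <- data.frame(lateral = c(16, 20, 24), depth = 4,
                      prominence = c(1, 1, 1))
  sel <- selectTriplet(cand3, p)
  expect_true(is.na(sel$rejection))
  expect_equal(sel$dl, 4)
  expect_equal(sel$dr, 4)
  expect_equal(sel$pose@a0, 20)
  # two candidates are not enough
  expect_equal(selectTriplet(cand3[1:2, ], p)$rejection, "too-few-peaks")
  # a spurious fourth peak far outside the pattern gate is ignored;
  # brute-force: of the four 3-subsets only the true one passes the gates
  cand4 <- rbind(cand3, data.frame(lateral = 39, depth = 4, prominence = 2))
  sel4 <- selectTriplet(cand4, p)
  expect_true(is.na(sel4$rejection))
  expect_equal(sel4$pose@a0, 20)
  expect_equal(sort(sel4$triplet$lateral), c(16, 20, 24))
  # all-triplets-gated: distances too wide for the pattern
  wide <- data.frame(lateral = c(0, 20, 40), depth = 4, prominence = 1)
  expect_equal(selectTriplet(wide, p)$rejection, "gate-failed")
})

test_that("slice pose recovers rendered poses and rejects empty slices", {
  p <- protoPattern()
  s <- renderSlice(NULL, probePose(0, 20, 20, 4), p,
                   imageGeometry(pixelSpacing = c(0.1, 0.1)))
  r <- slicePose(s, p)
  expect_true(r$accepted)
  expect_equal(r$pose@a0, 20, tolerance = 1e-3)
  expect_equal(r$pose@alpha, 0, tolerance = 1e-6)
  expect_equal(r$pose@xc, 20, tolerance = 1e-3)
  expect_equal(r$pose@yc, 4, tolerance = 0.1)
  # zeroed pattern channel -> rejection
  z <- paSlice(matrix(0, 50, 50), pixelSpacing = c(0.2, 0.2))
  rz <- slicePose(z, p)
  expect_false(rz$accepted)
  expect_equal(rz$rejection, "too-few-peaks")
})

test_that("pose decoding under peak jitter stays within the sensitivity bound", {
  # Monte-Carlo: jitter sigma 0.05 mm on each blob; the 95th percentile of
  # |a0 error| must stay under 0.5 mm (cf. the sensitivity of a0 to
  # distance perturbations: ~2.5 mm offset change per mm distance change)
  p <- protoPattern()
  set.seed(11)
  errs <- replicate(40, {
    s <- renderSlice(NULL, probePose(5 * pi / 180, 35, 20, 4), p,
                     imageGeometry(pixelSpacing = c(0.1, 0.1)),
                     noiseModel(blobJitterSd = 0.05),
                     seed = sample.int(1e6, 1))
    r <- slicePose(s, p)
    if (r$accepted) abs(r$pose@a0 - 35) else NA_real_
  })
  expect_true(all(!is.na(errs)))
  expect_lt(unname(quantile(errs, 0.95)), 0.5)
})

test_that("lateral translation shifts xc and leaves the pose unchanged", {
  p <- protoPattern()
  base <- slicePose(blobSlice(c(16, 20, 24)), p)
  shift <- slicePose(blobSlice(c(16, 20, 24) + 3), p)
  expect_equal(shift$pose@xc - base$pose@xc, 3, tolerance = 1e-6)
  expect_equal(shift$pose@alpha, base$pose@alpha, tolerance = 1e-6)
  expect_equal(shift$pose@a0, base$pose@a0, tolerance = 1e-6)
})

test_that("identical slices give identical results (determinism)", {
  p <- protoPattern()
  s <- blobSlice(c(14, 19, 23))
  expect_identical(slicePose(s, p), slicePose(s, p))
})

test_that("acceptance gates track the pattern extent on rendered sweeps", {
  p <- protoPattern()
  geom <- imageGeometry(pixelSpacing = c(0.2, 0.2))
  inside <- vapply(seq(5, 48, by = 5), function(a0)
    slicePose(renderSlice(NULL, probePose(0, a0, 20, 4), p, geom),
              p)$accepted, logical(1))
  expect_true(all(inside))
  # past the extent the pattern is simply not imaged -> rejection
  beyond <- slicePose(renderSlice(NULL, probePose(0, 58, 20, 4), p, geom), p)
  expect_false(beyond$accepted)
})

test_that("stack pose tables carry acceptance and rejection reasons", {
  p <- protoPattern()
  s1 <- blobSlice(c(16, 20, 24), index = 1L)
  s2 <- paSlice(matrix(0, 30, 30), pixelSpacing = c(0.2, 0.2), index = 2L)
  tbl <- stackPoses(list(s1, s2), p)
  expect_equal(tbl$accepted, c(TRUE, FALSE))
  expect_equal(tbl$rejection_reason[2], "too-few-peaks")
  expect_equal(tbl$a0_mm[1], 20, tolerance = 1e-3)
})
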