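# Detection, motion estimation/correction, gated assignment, Kalman linking.

test_that("a symmetric Gaussian blob is localized to sub-pixel precision", {
  px <- 0.05
  # blob at (x, z) = (1.23, 4.56) mm -> pixel units (z/px, x/px)
  f <- gaussFrame(120, 60, cbind(4.56 / px, 1.23 / px), sigma = 1.2)
  det <- detectMicrobubbles(f, px, relThreshold = 0.3, minSeparation = 0.1,
                            window = 7L)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x_mm - 1.23) / px, 0.1)
  expect_lt(abs(det$z_mm - 4.56) / px, 0.1)
})

test_that("detection separates distinct blobs and returns nothing on flat frames", {
  px <- 0.05
  f <- gaussFrame(100, 100, rbind(c(30, 30), c(70, 60)), sigma = 1.2,
                  amp = c(1, 0.8))
  det <- detectMicrobubbles(f, px, minSeparation = 0.2)
  expect_equal(nrow(det), 2L)
  expect_equal(nrow(detectMicrobubbles(matrix(0, 50, 50), px)), 0L)
  expect_equal(nrow(detectMicrobubbles(matrix(0.7, 50, 50), px)), 0L)
  # two blobs closer than minSeparation collapse to the brighter one
  f2 <- gaussFrame(100, 100, rbind(c(50, 50), c(50, 53)), sigma = 1.2,
                   amp = c(1, 0.6))
  det2 <- detectMicrobubbles(f2, px, minSeparation = 0.5)
  expect_equal(nrow(det2), 1L)
})

test_that("speckle tracking recovers a known rigid shift to sub-pixel accuracy", {
  tr <- straightTree(c(1, 3), c(5, 3), bbox = rbind(c(0, 0), c(6.4, 6.4)))
  acq <- acquisitionParams(nFrames = 30L, motionAmplitude = 0.25,
                           motionPeriod = 1.5, noiseSigma = 0.01, seed = 6L)
  sim <- simulateMbMovie(tr, acq)
  mf <- estimateMotion(sim$bmode, 1L, blockSize = 1.2, searchRadius = 0.4)
  err <- (displacement(mf) - trueMotion(sim$groundTruth)) / 0.05
  expect_lt(sqrt(mean(err^2)), 0.25)
  expect_equal(displacement(mf)[1L, ], c(dx = 0, dz = 0))
  expect_true(all(motionConfidence(mf)[-1L] > 0.5))
})

test_that("uncorrelated noise frames are flagged low-confidence and bounded", {
  set.seed(40)
  arr <- array(stats::runif(64 * 64 * 4), dim = c(64, 64, 4))
  st <- FrameStack(arr, 0.05, 55, "bmode")
  mf <- estimateMotion(st, 1L, blockSize = 0.6, searchRadius = 0.3)
  expect_true(all(motionConfidence(mf)[-1L] < 0.5))
  expect_true(all(abs(displacement(mf)) <= 0.3 + 1e-9))
})

test_that("position correction subtracts the per-frame displacement", {
  det <- data.frame(frame = c(1L, 2L, 2L), x_mm = c(1, 2, 3),
                    z_mm = c(4, 5, 6))
  zero <- new("MotionField", displacement = matrix(0, 3, 2),
              referenceIndex = 1L, confidence = rep(1, 3))
  expect_identical(correctPositions(det, zero), det)
  d <- matrix(0, 3, 2); d[2L, ] <- c(0.2, -0.1); d[3L, ] <- c(0.2, -0.1)
  mf <- new("MotionField", displacement = d, referenceIndex = 1L,
            confidence = rep(1, 3))
  cor <- correctPositions(det, mf)
  expect_equal(cor$x_mm, c(1, 1.8, 2.8))
  expect_equal(cor$z_mm, c(4, 5.1, 6.1))
  det$frame[1L] <- 9L
  expect_error(correctPositions(det, mf), "cover")
})

test_that("gated assignment equals the brute-force optimum on random instances", {
  set.seed(101)
  for (k in 1:120) {
    n <- sample(1:4, 1L); m <- sample(1:4, 1L)
    cost <- matrix(stats::runif(n * m, 0, 2), n, m)
    gate <- stats::runif(1, 0.3, 1.6)
    a <- solveAssignment(cost, gate)
    matched <- which(!is.na(a))
    expect_true(!anyDuplicated(a[matched]))
    expect_true(all(cost[cbind(matched, a[matched])] <= gate))
    bf <- bruteAssign(cost, gate)
    expect_equal(length(matched), bf$card)
    expect_equal(sum(cost[cbind(matched, a[matched])]), bf$cost,
                 tolerance = 1e-9)
  }
})

test_that("tracks require at least minTrackLength consecutive frames", {
  d2 <- lineDetections(1:2, c(1, 1), c(0.1, 0))
  expect_equal(nTracks(trackMicrobubbles(d2, trackerParams(), 55)), 0L)
  d3 <- lineDetections(1:3, c(1, 1), c(0.1, 0))
  expect_equal(nTracks(trackMicrobubbles(d3, trackerParams(), 55)), 1L)
  d10 <- lineDetections(1:10, c(1, 1), c(0.1, 0))
  ts <- trackMicrobubbles(d10, trackerParams(), 55)
  expect_equal(nTracks(ts), 1L)
  expect_equal(nrow(tracks(ts)), 10L)
  expect_equal(tracks(ts)$frame, 1:10)
  # empty input
  expect_equal(nTracks(trackMicrobubbles(d10[0, ], trackerParams(), 55)), 0L)
})

test_that("a gap in the detection stream terminates the track", {
  d <- lineDetections(c(1:4, 6:9), c(1, 1), c(0.1, 0))
  d$x_mm[5:8] <- 1 + 0.1 * (5:8)   # keep positions on the same line
  ts <- trackMicrobubbles(d, trackerParams(nHierarchyPasses = 1L), 55)
  expect_equal(nTracks(ts), 2L)
  byid <- split(tracks(ts)$frame, tracks(ts)$track_id)
  expect_true(all(vapply(byid, function(f) all(diff(f) == 1L), logical(1))))
})

test_that("parallel bubbles separated well beyond the gate never switch identity", {
  gate <- 20 / 55
  dA <- lineDetections(1:12, c(1, 1), c(0.15, 0))
  dB <- lineDetections(1:12, c(1, 1 + 3 * gate), c(0.15, 0))
  det <- rbind(dA, dB)
  ts <- trackMicrobubbles(det, trackerParams(), 55)
  expect_equal(nTracks(ts), 2L)
  for (id in unique(tracks(ts)$track_id)) {
    z <- tracks(ts)$z_mm[tracks(ts)$track_id == id]
    expect_equal(length(unique(round(z, 9))), 1L)  # stayed in its own lane
  }
})

test_that("no detection is claimed by more than one track", {
  set.seed(33)
  det <- do.call(rbind, lapply(1:8, function(f)
    data.frame(frame = f, x_mm = stats::runif(4, 0, 2),
               z_mm = stats::runif(4, 0, 2))))
  ts <- trackMicrobubbles(det, trackerParams(minTrackLength = 1L), 55)
  df <- tracks(ts)
  key <- paste(df$frame, df$x_mm, df$z_mm)
  expect_true(!anyDuplicated(key))
  # every emitted point is one of the input detections
  expect_true(all(key %in% paste(det$frame, det$x_mm, det$z_mm)))
})

test_that("the second hierarchy pass links leftovers with a widened gate", {
  gate <- 20 / 55                      # ~0.364 mm
  step <- gate * 1.4                   # too fast for pass 1, fine for pass 2
  d <- lineDetections(1:6, c(1, 1), c(step, 0))
  one <- trackMicrobubbles(d, trackerParams(nHierarchyPasses = 1L), 55)
  expect_equal(nTracks(one), 0L)
  two <- trackMicrobubbles(d, trackerParams(nHierarchyPasses = 2L,
                                            passGateScale = 2), 55)
  expect_equal(nTracks(two), 1L)
  expect_equal(nrow(tracks(two)), 6L)
})
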