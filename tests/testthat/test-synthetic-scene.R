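# Synthetic scene generator: trees, movies, volumes and their ground truth.

test_that("a straight unbranched tree has tortuosity exactly 1 and is deterministic", {
  tr1 <- generateVesselTree(1, branchingDepth = 0, tortuosityAmp = 0, seed = 7)
  expect_length(segments(tr1), 1L)
  expect_equal(segmentTortuosity(tr1), 1, tolerance = 1e-12)
  tr2 <- generateVesselTree(1, branchingDepth = 0, tortuosityAmp = 0, seed = 7)
  expect_identical(segments(tr1), segments(tr2))
  tr3 <- generateVesselTree(1, branchingDepth = 0, tortuosityAmp = 0, seed = 8)
  expect_false(identical(segments(tr1), segments(tr3)))
})

test_that("sinusoidal perturbation reproduces the analytic arc-length tortuosity", {
  amp <- 0.6
  tr <- generateVesselTree(1, 0, tortuosityAmp = amp, seed = 3,
                           pointsPerSegment = 400L)
  p <- segments(tr)[[1L]]
  L <- sqrt(sum((p[nrow(p), ] - p[1L, ])^2))
  k <- 2 * pi / L
  analytic <- stats::integrate(function(s) sqrt(1 + (amp * k * cos(k * s))^2),
                               0, L, rel.tol = 1e-10)$value / L
  expect_equal(segmentTortuosity(tr), analytic, tolerance = 0.01)
})

test_that("tortuosity is monotonically non-decreasing in the perturbation amplitude", {
  tort <- vapply(c(0, 0.15, 0.3, 0.6), function(a)
    mean(segmentTortuosity(generateVesselTree(3, 1, a, seed = 5))), numeric(1))
  expect_true(all(diff(tort) >= 0))
  expect_gt(tort[4L], tort[1L])
})

test_that("tree generation rejects invalid parameters and satisfies its invariants", {
  expect_error(generateVesselTree(0), "nRootVessels")
  expect_error(generateVesselTree(2, tortuosityAmp = -1), "tortuosityAmp")
  tr <- generateVesselTree(4, branchingDepth = 2, tortuosityAmp = 0.1, seed = 2)
  expect_true(validObject(tr))   # >= 2 points, radii > 0, connectivity, bbox
  expect_true(all(segmentRadii(tr) > 0))
  # children start on a point of their parent polyline
  par <- tr@parent
  for (s in which(par > 0L)) {
    d2 <- colSums((t(segments(tr)[[par[s]]]) - segments(tr)[[s]][1L, ])^2)
    expect_lt(min(d2), 1e-12)
  }
})

test_that("root-lineage subsetting rarefies the tree and keeps it valid", {
  tr <- generateVesselTree(10, branchingDepth = 1, seed = 4)
  sub <- subsetVesselTree(tr, keep = 0.6, seed = 9)
  expect_true(validObject(sub))
  expect_lt(length(segments(sub)), length(segments(tr)))
  ratio <- length(segments(sub)) / length(segments(tr))
  expect_gt(ratio, 0.35)
  expect_lt(ratio, 0.85)
})

test_that("noiseless bubbles render on the centerline and influx is Poisson", {
  bbox <- rbind(c(0, 0), c(6.4, 6.4))
  tr <- straightTree(c(1, 3.2), c(5.4, 3.2), bbox = bbox)
  acq <- acquisitionParams(nFrames = 20L, pixelSize = 0.05, psfSigma = 0.1,
                           mbInfluxRate = 2, noiseSigma = 0,
                           motionAmplitude = 0, seed = 21L)
  sim <- simulateMbMovie(tr, acq)
  gt <- trueDetections(sim$groundTruth)
  for (f in unique(gt$frame)) {
    img <- frames(sim$contrast)[, , f]
    sub <- gt[gt$frame == f, ]
    if (nrow(sub) != 1L) next
    pk <- which(img == max(img), arr.ind = TRUE)[1L, ]
    # blob maximum on the centerline within half a pixel
    expect_lt(abs((pk[1L] - 0.5) * 0.05 - sub$z_mm), 0.05 / 2 + 1e-9)
    expect_lt(abs((pk[2L] - 0.5) * 0.05 - sub$x_mm), 0.05 / 2 + 1e-9)
  }
  # Poisson influx: mean r*T, total within 3 sd (single-file thinning off
  # so the raw entry process is what is counted)
  acq2 <- acquisitionParams(nFrames = 550L, mbInfluxRate = 10, noiseSigma = 0,
                            motionAmplitude = 0, minEntryGap = 0, seed = 5L)
  sim2 <- simulateMbMovie(tr, acq2)
  rT <- 10 * 550 / 55
  nb <- length(unique(trueDetections(sim2$groundTruth)$bubble_id))
  expect_lt(abs(nb - rT), 3 * sqrt(rT))
})

test_that("injected sinusoidal motion is recorded exactly in the ground truth", {
  tr <- straightTree(c(1, 3), c(5, 3), bbox = rbind(c(0, 0), c(6.4, 6.4)))
  acq <- acquisitionParams(nFrames = 40L, motionAmplitude = 0.3,
                           motionPeriod = 2, motionAngleDeg = 70, seed = 2L)
  sim <- simulateMbMovie(tr, acq)
  tt <- (seq_len(40L) - 1L) / 55
  expected <- 0.3 * sin(2 * pi * tt / 2)
  ang <- 70 * pi / 180
  expect_equal(trueMotion(sim$groundTruth)[, 1L], expected * cos(ang))
  expect_equal(trueMotion(sim$groundTruth)[, 2L], expected * sin(ang))
})

test_that("movie simulation is deterministic and rejects empty trees", {
  tr <- straightTree(c(1, 2), c(4, 5), bbox = rbind(c(0, 0), c(6.4, 6.4)))
  acq <- acquisitionParams(nFrames = 10L, seed = 77L)
  s1 <- simulateMbMovie(tr, acq)
  s2 <- simulateMbMovie(tr, acq)
  expect_identical(frames(s1$contrast), frames(s2$contrast))
  expect_identical(frames(s1$bmode), frames(s2$bmode))
  expect_identical(trueDetections(s1$groundTruth), trueDetections(s2$groundTruth))
})

test_that("rendered cylinder volume matches the analytic voxel count within 5%", {
  bbox <- rbind(c(0, 0, 0), c(4, 4, 6))
  tr <- VesselTree(list(rbind(c(2, 2, 0.5), c(2, 2, 5.5))), 500, 5, "CO", 0L,
                   bbox)
  rnd <- renderUctVolume(tr, voxelSizeUm = 100, noiseSigma = 0)
  fg <- radiusField(rnd$radius) > 0
  analytic <- pi * 5^2 * (5 / 0.1)       # r = 5 vox, length 50 vox
  expect_lt(abs(sum(fg) / analytic - 1), 0.05)
  # intensity volume mirrors the radius field
  expect_identical(volumeData(rnd$volume) > 0.45, fg)
  # region far from the tube is pure background
  expect_true(all(volumeData(rnd$volume)[1:5, 1:5, ] == 0.1))
  expect_error(renderUctVolume(tr, voxelSizeUm = -1), "voxelSizeUm")
})

test_that("volume rendering with noise is seed-deterministic", {
  bbox <- rbind(c(0, 0, 0), c(3, 3, 3))
  tr <- VesselTree(list(rbind(c(1.5, 1.5, 0.3), c(1.5, 1.5, 2.7))), 300, 5,
                   "CO", 0L, bbox)
  v1 <- renderUctVolume(tr, 100, noiseSigma = 0.05, seed = 9L)
  v2 <- renderUctVolume(tr, 100, noiseSigma = 0.05, seed = 9L)
  expect_identical(volumeData(v1$volume), volumeData(v2$volume))
  v3 <- renderUctVolume(tr, 100, noiseSigma = 0.05, seed = 10L)
  expect_false(identical(volumeData(v1$volume), volumeData(v3$volume)))
})

test_that("analytic regional density agrees with lumen rasterization within 5%", {
  # radius 150 um on a 50 um grid = 3 px: above the 2 px validity floor.
  # The analytic mode sums per-vessel areas (it ignores lumen overlap),
  # so the comparison uses a configuration whose vessels do not cross.
  tr <- generateVesselTree(6, branchingDepth = 0, tortuosityAmp = 0, seed = 5,
                           rootRadiusUm = 150)
  roi <- regionBandMask(c(12.8, 12.8), 0.05)
  lum <- trueRegionDensity(tr, roi, 0.05, mode = "lumen")
  ana <- trueRegionDensity(tr, roi, 0.05, mode = "analytic")
  for (g in c("CO", "OM")) {
    expect_lt(abs(lum[[g]] - ana[[g]]) / ana[[g]], 0.05)
  }
})
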