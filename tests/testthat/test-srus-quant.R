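# Track accumulation, patch density, distance-metric tortuosity.

hTrack <- function(id, x0, x1, z, n = 2) {
  data.frame(track_id = id, frame = seq_len(n),
             x_mm = seq(x0, x1, length.out = n), z_mm = z)
}

test_that("a horizontal track fills ~L/pixel pixels with direction 0 (pi reversed)", {
  h <- 0.025
  img <- accumulateTracks(hTrack(1, 0.2, 3.2, 1.0), h, extent = c(4, 2))
  n <- sum(trackRaster(img))
  expect_lte(abs(n - 3 / h), 1)
  expect_true(all(abs(directionMap(img)[trackRaster(img)]) < 1e-9))
  rev <- accumulateTracks(hTrack(1, 3.2, 0.2, 1.0), h, extent = c(4, 2))
  expect_identical(trackRaster(rev), trackRaster(img))
  expect_true(all(abs(abs(directionMap(rev)[trackRaster(rev)]) - pi) < 1e-9))
})

test_that("crossing tracks union their pixels and circular-average their angles", {
  h <- 0.025
  t1 <- hTrack(1, 0.2, 1.8, 1.0)                       # angle 0
  t2 <- data.frame(track_id = 2, frame = 1:2,           # angle pi/2 (down +z)
                   x_mm = 1.0125, z_mm = c(0.2, 1.8))
  img <- accumulateTracks(rbind(t1, t2), h, extent = c(2, 2))
  i1 <- accumulateTracks(t1, h, extent = c(2, 2))
  i2 <- accumulateTracks(t2, h, extent = c(2, 2))
  expect_identical(trackRaster(img), trackRaster(i1) | trackRaster(i2))
  crossing <- trackRaster(i1) & trackRaster(i2)
  expect_true(any(crossing))
  # circular mean of 0 and pi/2 is pi/4
  expect_true(all(abs(directionMap(img)[crossing] - pi / 4) < 1e-9))
  # empty input -> empty raster
  e <- accumulateTracks(tracks(TrackSet(t1[0, ], 55)), h, extent = c(2, 2))
  expect_false(any(trackRaster(e)))
})

test_that("patch density honors its bounds and the exact end-member values", {
  h <- 0.025
  roi <- matrix("CO", 160, 160)                         # 4 x 4 mm, all cortex
  full <- new("SRUSImage", raster = matrix(TRUE, 160, 160),
              direction = matrix(0, 160, 160), pixelSize = h,
              origin = c(0, 0))
  res <- computePatchDensity(full, roi, "CO", patchSide = 2, overlap = 0.5)
  expect_true(all(res$patches$density == 1))
  expect_identical(res$meanDensityPct, 100)
  emptyImg <- new("SRUSImage", raster = matrix(FALSE, 160, 160),
                  direction = matrix(NA_real_, 160, 160), pixelSize = h,
                  origin = c(0, 0))
  res0 <- computePatchDensity(emptyImg, roi, "CO")
  expect_true(all(res0$patches$density == 0))
  expect_identical(res0$meanDensityPct, 0)
  expect_error(computePatchDensity(full, roi, "IM"), "absent")
})

test_that("a checkerboard raster yields density 0.5 in every patch", {
  h <- 0.025
  n <- 160
  ras <- outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 2L == 0L)
  img <- new("SRUSImage", raster = ras,
             direction = ifelse(ras, 0, NA_real_), pixelSize = h,
             origin = c(0, 0))
  roi <- matrix("CO", n, n)
  res <- computePatchDensity(img, roi, "CO", patchSide = 2, overlap = 0.5)
  expect_true(all(abs(res$patches$density - 0.5) < 1e-12))
  expect_equal(res$meanDensityPct, 50)
})

test_that("density is order-invariant, translation-invariant and monotone in tracks", {
  h <- 0.025
  # generic (off-boundary) coordinates: points landing exactly on pixel
  # edges are knife-edge cases where a float translation may flip one
  # supercover pixel
  tA <- hTrack(1, 0.3118, 2.4118, 0.8118, n = 5)
  tB <- data.frame(track_id = 2, frame = 1:4,
                   x_mm = c(1.011, 1.411, 1.911, 2.311),
                   z_mm = c(0.411, 0.911, 1.211, 1.911))
  roi <- matrix("CO", 120, 120)
  dens <- function(df, org = c(0, 0)) {
    img <- accumulateTracks(df, h, extent = c(3, 3), origin = org)
    computePatchDensity(img, roi, "CO", patchSide = 1, overlap = 0.5)$meanDensityPct
  }
  expect_equal(dens(rbind(tA, tB)), dens(rbind(tB, tA)))
  # rigid translation of tracks together with the grid origin
  sh <- c(0.4, -0.2)
  tAs <- tA; tAs$x_mm <- tA$x_mm + sh[1L]; tAs$z_mm <- tA$z_mm + sh[2L]
  tBs <- tB; tBs$x_mm <- tB$x_mm + sh[1L]; tBs$z_mm <- tB$z_mm + sh[2L]
  expect_equal(dens(rbind(tAs, tBs), org = sh), dens(rbind(tA, tB)))
  expect_gte(dens(rbind(tA, tB)), dens(tA))
  expect_gte(dens(tA), 0)
})

test_that("distance-metric tortuosity reproduces its closed forms", {
  roi <- matrix("CO", 120, 120)
  mk <- function(xs, zs) data.frame(track_id = 1, frame = seq_along(xs),
                                    x_mm = xs, z_mm = zs)
  col <- computeTortuosity(mk(c(0.5, 1.5, 2.5), c(1, 1, 1)), roi, "CO")
  expect_identical(col$perTrack$tortuosity, 1)
  ra <- computeTortuosity(mk(c(0.5, 1.5, 1.5), c(1, 1, 2)), roi, "CO")
  expect_equal(ra$perTrack$tortuosity, sqrt(2), tolerance = 1e-12)
  th <- seq(0, pi, length.out = 100L)
  hc <- computeTortuosity(mk(1.5 + cos(th), 1.5 + sin(th)), roi, "CO")
  expect_equal(hc$perTrack$tortuosity, pi / 2, tolerance = 1e-3)
})

test_that("tortuosity is >= 1, degenerate chords are excluded and tallied", {
  roi <- matrix("CO", 120, 120)
  set.seed(8)
  df <- do.call(rbind, lapply(1:20, function(id) {
    n <- sample(3:8, 1L)
    data.frame(track_id = id, frame = seq_len(n),
               x_mm = cumsum(stats::runif(n, 0.02, 0.2)),
               z_mm = cumsum(stats::runif(n, -0.1, 0.12)) + 1.5)
  }))
  res <- computeTortuosity(df, roi, "CO")
  expect_true(all(res$perTrack$tortuosity >= 1 - 1e-12))
  loop <- data.frame(track_id = 99, frame = 1:5,
                     x_mm = c(1, 1.2, 1.4, 1.2, 1.000001),
                     z_mm = c(1, 1.2, 1.0, 0.8, 1.000001))
  res2 <- computeTortuosity(rbind(df, loop), roi, "CO")
  expect_equal(res2$nExcluded, 1L)
  expect_equal(nrow(res2$perTrack), nrow(res$perTrack))
})

test_that("tracks are attributed to the region holding most of their points", {
  roi <- rbind(matrix("CO", 60, 120), matrix("OM", 60, 120))  # split at z = 1.5
  df <- data.frame(track_id = 1, frame = 1:5, x_mm = 1.5,
                   z_mm = c(1.2, 1.4, 1.6, 1.8, 2.0))          # 3 of 5 in OM
  expect_equal(nrow(computeTortuosity(df, roi, "OM", 0.025)$perTrack), 1L)
  expect_equal(nrow(computeTortuosity(df, roi, "CO", 0.025)$perTrack), 0L)
})

test_that("sum-of-angles metric is zero for straight tracks and larger for bent ones", {
  straight <- data.frame(track_id = 1, frame = 1:5, x_mm = 1:5 * 0.1, z_mm = 1)
  bent <- data.frame(track_id = 2, frame = 1:5,
                     x_mm = c(0.1, 0.2, 0.3, 0.3, 0.3),
                     z_mm = c(1, 1, 1, 1.1, 1.2))
  res <- sumOfAnglesTortuosity(rbind(straight, bent))
  expect_equal(res$soam[res$track_id == 1], 0)
  expect_gt(res$soam[res$track_id == 2], 0)
})
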