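# Micro-CT branch: region growing, label interpolation, vessel masks,
# local thickness, radius partition, regional density.

test_that("region growing recovers a bright ellipsoid and respects connectivity", {
  d <- c(40L, 40L, 40L)
  ctr <- c(20.5, 20.5, 20.5); ax <- c(14, 11, 9)
  ii <- slice.index(array(0, d), 1L); jj <- slice.index(array(0, d), 2L)
  kk <- slice.index(array(0, d), 3L)
  ell <- ((ii - ctr[1L]) / ax[1L])^2 + ((jj - ctr[2L]) / ax[2L])^2 +
    ((kk - ctr[3L]) / ax[3L])^2 <= 1
  set.seed(2)
  v <- array(stats::runif(prod(d), 0, 0.3), dim = d)
  v[ell] <- stats::runif(sum(ell), 0.6, 1)
  vol <- Volume3D(v, 26.5)
  m <- segmentKidney(vol, c(20, 20, 20), 0.5, closingRadius = 0)
  expect_identical(m, ell)
  # closing can only add voxels (here the ellipsoid is already closed)
  m2 <- segmentKidney(vol, c(20, 20, 20), 0.5, closingRadius = 2)
  expect_true(all(m2[ell]))
  expect_error(segmentKidney(vol, c(1, 1, 1), 0.5), "below the threshold")
  expect_error(segmentKidney(vol, c(20, 20, 20), 2), "maximum intensity")
  # two disjoint blobs: only the seeded one is grown
  v2 <- array(0, d); v2[5:10, 5:10, 5:10] <- 1; v2[25:30, 25:30, 25:30] <- 1
  m3 <- segmentKidney(Volume3D(v2, 26.5), c(7, 7, 7), 0.5, closingRadius = 0)
  expect_equal(sum(m3), 216L)
  expect_false(any(m3[25:30, 25:30, 25:30]))
})

test_that("region masks hold exact set relations", {
  rm <- syntheticRegionMasks(c(30L, 30L, 30L))
  expect_true(all(medullaMask(rm) | !medullaMask(rm)))
  expect_false(any(cortexMask(rm) & medullaMask(rm)))
  expect_identical(cortexMask(rm) | medullaMask(rm), kidneyMask(rm))
  expect_true(all(kidneyMask(rm)[medullaMask(rm)]))
})

test_that("label interpolation is exact on labeled slices and linear between them", {
  disk <- function(r, n = 50) {
    i <- slice.index(matrix(0, n, n), 1L); j <- slice.index(matrix(0, n, n), 2L)
    (i - 25)^2 + (j - 25)^2 <= r^2
  }
  lab <- array(0L, c(50, 50, 11))
  lab[, , 1][disk(10)] <- 1L
  lab[, , 11][disk(20)] <- 1L
  dense <- interpolateLabels(lab, c(1, 11))
  expect_identical(dense[, , 1] == 1L, disk(10))
  expect_identical(dense[, , 11] == 1L, disk(20))
  # concentric disks: SDF interpolation gives radius 15 +- 1 voxel at midpoint
  req <- sqrt(sum(dense[, , 6] == 1L) / pi)
  expect_lt(abs(req - 15), 1)
  # identical labeled slices -> constant fill
  lab2 <- array(0L, c(30, 30, 6))
  lab2[, , 1][disk(8, 30)] <- 1L; lab2[, , 6][disk(8, 30)] <- 1L
  d2 <- interpolateLabels(lab2, c(1, 6))
  for (k in 2:5) expect_identical(d2[, , k], d2[, , 1])
  # all slices labeled -> identity
  lab3 <- array(1L, c(10, 10, 3)); lab3[5, 5, ] <- 2L
  expect_identical(interpolateLabels(lab3, 1:3), lab3)
  # a single labeled slice replicates with a warning
  lab4 <- array(0L, c(20, 20, 4)); lab4[, , 2][disk(5, 20)] <- 1L
  expect_warning(d4 <- interpolateLabels(lab4, 2), "single")
  expect_identical(d4[, , 4], d4[, , 2])
})

test_that("vessel segmentation is exact thresholding inside the organ mask", {
  bbox <- rbind(c(0, 0, 0), c(3, 3, 4))
  tr <- VesselTree(list(rbind(c(1.5, 1.5, 0.3), c(1.5, 1.5, 3.7))), 300, 5,
                   "CO", 0L, bbox)
  rnd <- renderUctVolume(tr, 100, noiseSigma = 0)
  fg <- radiusField(rnd$radius) > 0
  kid <- array(TRUE, dim(fg))
  expect_identical(segmentVessels(rnd$volume, kid, 0.45), fg)
  expect_warning(empty <- segmentVessels(rnd$volume, kid, 0.9),
                 "intensity range")   # above the vessel intensity
  expect_false(any(empty))
  # monotone: vessel count non-increasing in the threshold
  noisy <- renderUctVolume(tr, 100, noiseSigma = 0.1, seed = 3L)$volume
  counts <- vapply(seq(0.2, 0.9, by = 0.1),
                   function(th) sum(segmentVessels(noisy, kid, th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("local thickness matches the brute-force inscribed-sphere oracle", {
  mask <- cylinderMask(16, 12, radius = 4)
  lt <- radiusField(estimateLocalRadius(mask))
  oracle <- bruteLocalThickness(mask)
  expect_equal(lt, oracle, tolerance = 1e-12)
  # an isolated voxel has unit distance to background
  single <- array(FALSE, c(7, 7, 7)); single[4, 4, 4] <- TRUE
  lt1 <- radiusField(estimateLocalRadius(single))
  expect_equal(lt1[4, 4, 4], 1)
  expect_equal(sum(lt1 > 0), 1L)
})

test_that("two fused cylinders give a bimodal radius histogram", {
  # axes 11 voxels apart so the radius-3 tube touches the radius-8 tube
  ii <- seq_len(36) - 0.5
  d1 <- outer((ii - 22)^2, (ii - 18)^2, "+")     # axis 1 at (22, 18)
  d2 <- outer((ii - 11)^2, (ii - 18)^2, "+")     # axis 2 at (11, 18)
  sl <- d1 <= 8^2 | d2 <= 3^2
  mask <- array(rep(sl, 14), dim = c(36, 36, 14))
  lt <- radiusField(estimateLocalRadius(mask))
  vals <- lt[lt > 0]
  expect_gt(sum(abs(vals - 7.5) < 1.3), 0)
  expect_gt(sum(abs(vals - 2.6) < 1.0), 0)
  # modes are separated: little mass midway
  expect_lt(mean(vals > 4.2 & vals < 5.8), 0.12)
})

test_that("local thickness is invariant to translation and axis permutation", {
  m <- array(FALSE, c(14, 14, 14))
  m[4:9, 5:9, 3:11] <- TRUE
  lt <- radiusField(estimateLocalRadius(m))
  sh <- array(FALSE, c(14, 14, 14))
  sh[6:11, 6:10, 4:12] <- TRUE
  lts <- radiusField(estimateLocalRadius(sh))
  expect_equal(lt[4:9, 5:9, 3:11], lts[6:11, 6:10, 4:12])
  pm <- aperm(m, c(3, 1, 2))
  ltp <- radiusField(estimateLocalRadius(pm))
  expect_equal(aperm(lt, c(3, 1, 2)), ltp)
})

test_that("radius partition splits the mask exactly at the threshold", {
  mask <- cylinderMask(22, 12, radius = 8)
  rmap <- estimateLocalRadius(mask)
  pp <- partitionByRadius(rmap, 6)
  expect_identical(pp$small | pp$large, mask)       # union = vessel mask
  expect_false(any(pp$small & pp$large))            # disjoint
  expect_true(all(pp$large[mask]))                  # whole cylinder is 'large'
  pp2 <- partitionByRadius(rmap, 20)
  expect_false(any(pp2$large))
  expect_identical(pp2$small, mask)
})

test_that("regional density recovers the analytic cylinder volume fraction", {
  bbox <- rbind(c(0, 0, 0), c(4, 4, 6))
  tr <- VesselTree(list(rbind(c(2, 2, 0.5), c(2, 2, 5.5))), 400, 5, "CO", 0L,
                   bbox)
  rnd <- renderUctVolume(tr, 100, noiseSigma = 0)
  vm <- radiusField(rnd$radius) > 0
  rmap <- estimateLocalRadius(vm)
  pp <- partitionByRadius(rmap, 10)   # r = 4 voxels: everything is small
  region <- array(TRUE, dim(vm))
  res <- computeRegionDensity(pp$small, pp$large, region, "all", 10)
  analytic <- (pi * 4^2 * 50) / prod(dim(vm))
  expect_lt(abs(res$density - analytic) / analytic, 0.05)
  expect_identical(res$small_voxels, sum(pp$small & region))
  expect_identical(res$region_voxels, sum(region & !pp$large))
  # end members
  none <- computeRegionDensity(array(FALSE, dim(vm)), array(FALSE, dim(vm)),
                               region)
  expect_identical(none$density, 0)
  all1 <- computeRegionDensity(region, array(FALSE, dim(vm)), region)
  expect_identical(all1$density, 1)
  expect_error(computeRegionDensity(pp$small, region, region), "empty")
})
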