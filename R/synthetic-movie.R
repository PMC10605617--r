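# Microbubble movie simulation and micro-CT-like volume rendering.

#' Simulate a contrast + B-mode microbubble acquisition over a vessel tree
#'
#' Microbubbles enter the scene as a Poisson process at
#' `mbInfluxRate` bubbles/s (entry segment chosen uniformly), advect as
#' plug flow along the segment centerline at the segment's flow speed,
#' and leave at the far end. Entries into the same segment closer in
#' time than `minEntryGap` are thinned (the earlier bubble is kept):
#' microvessels carry bubbles in single file, and two bubbles riding the
#' same centerline within one point-spread width are unphysical and
#' unresolvable by any localization scheme. Each contrast frame renders every live
#' bubble as an isotropic Gaussian blob of `psfSigma` plus i.i.d.
#' Gaussian noise. A global sinusoidal rigid translation
#' (ventilation-like, amplitude `motionAmplitude`, period `motionPeriod`)
#' displaces both the contrast and the B-mode frames; the B-mode stack is
#' a fixed Gaussian-spot speckle texture undergoing the same translation,
#' interleaved 1:1 with the contrast frames. The returned
#' [GroundTruth-class] records exact bubble positions (pre-motion),
#' per-bubble trajectories, the injected motion and the generating tree's
#' per-segment tortuosity.
#'
#' @param tree a 2D [VesselTree-class] (or a tree whose first two
#'   coordinates are used).
#' @param acq an [AcquisitionParams-class].
#' @return list with elements `contrast` and `bmode` ([FrameStack-class])
#'   and `groundTruth` ([GroundTruth-class]).
#' @export
simulateMbMovie <- function(tree, acq = acquisitionParams()) {
  if (length(segments(tree)) == 0L) stop("empty vessel tree")
  bb <- boundingBox(tree)
  lo <- bb[1L, 1:2]; hi <- bb[2L, 1:2]
  px <- acq@pixelSize
  nz <- ceiling((hi[2L] - lo[2L]) / px)
  nx <- ceiling((hi[1L] - lo[1L]) / px)
  nf <- acq@nFrames
  fr <- acq@frameRate
  Ttot <- nf / fr
  ang <- acq@motionAngleDeg * pi / 180
  mdir <- c(cos(ang), sin(ang))

  withSeed(acq@seed, {
    polys <- lapply(segments(tree), function(p) p[, 1:2, drop = FALSE])
    plens <- vapply(polys, polylineLength, numeric(1))
    nb <- stats::rpois(1L, acq@mbInfluxRate * Ttot)
    entry <- sort(stats::runif(nb, 0, Ttot))
    segid <- if (nb) sample.int(length(polys), nb, replace = TRUE) else integer()
    if (acq@minEntryGap > 0 && nb > 1L) {
      # single-file vessels: thin same-segment entries closer than the
      # minimum gap (keep the earlier bubble)
      keep <- logical(nb)
      lastKept <- rep(-Inf, length(polys))
      for (b in seq_len(nb)) {
        if (entry[b] - lastKept[segid[b]] >= acq@minEntryGap) {
          keep[b] <- TRUE
          lastKept[segid[b]] <- entry[b]
        }
      }
      entry <- entry[keep]
      segid <- segid[keep]
      nb <- length(entry)
    }
    amp <- stats::runif(nb, 0.7, 1)

    tfr <- (seq_len(nf) - 1L) / fr
    mot <- outer(acq@motionAmplitude *
                   sin(2 * pi * tfr / acq@motionPeriod), mdir)
    colnames(mot) <- c("dx", "dz")

    det <- vector("list", nf)
    frames <- array(0, dim = c(nz, nx, nf))
    for (f in seq_len(nf)) {
      t <- tfr[f]
      live <- which(entry <= t &
                      (t - entry) * abs(tree@flowSpeed[segid]) <= plens[segid])
      if (length(live)) {
        pos <- t(vapply(live, function(b) {
          s <- (t - entry[b]) * abs(tree@flowSpeed[segid[b]])
          pointAlongPolyline(polys[[segid[b]]], s)
        }, numeric(2)))
        det[[f]] <- data.frame(frame = f, x_mm = pos[, 1L], z_mm = pos[, 2L],
                               bubble_id = live)
        shifted <- pos + rep(mot[f, ], each = nrow(pos))
        base <- matrix(0, nz, nx)
        img <- cpp_render_spots(nz, nx,
                                (shifted[, 2L] - lo[2L]) / px,
                                (shifted[, 1L] - lo[1L]) / px,
                                amp[live], acq@psfSigma / px, base)
      } else {
        det[[f]] <- data.frame(frame = integer(), x_mm = numeric(),
                               z_mm = numeric(), bubble_id = integer())
        img <- matrix(0, nz, nx)
      }
      if (acq@noiseSigma > 0)
        img <- img + matrix(stats::rnorm(nz * nx, 0, acq@noiseSigma), nz, nx)
      frames[, , f] <- img
    }
    detections <- do.call(rbind, det)

    trk <- detections[order(detections$bubble_id, detections$frame),
                      c("bubble_id", "frame", "x_mm", "z_mm")]
    rownames(trk) <- NULL

    # B-mode speckle: fixed analytic Gaussian-spot texture, re-rendered
    # under each frame's translation so sub-pixel shifts are exact.
    nspots <- round(0.02 * nz * nx)
    sx <- stats::runif(nspots, lo[1L] - 1, hi[1L] + 1)
    sz <- stats::runif(nspots, lo[2L] - 1, hi[2L] + 1)
    samp <- stats::runif(nspots, 0.1, 0.6)
    bframes <- array(0, dim = c(nz, nx, nf))
    for (f in seq_len(nf)) {
      base <- matrix(0, nz, nx)
      img <- cpp_render_spots(nz, nx, (sz + mot[f, 2L] - lo[2L]) / px,
                              (sx + mot[f, 1L] - lo[1L]) / px,
                              samp, 1.6, base)
      if (acq@noiseSigma > 0)
        img <- img + matrix(stats::rnorm(nz * nx, 0, acq@noiseSigma), nz, nx)
      bframes[, , f] <- img
    }

    gt <- new("GroundTruth", detections = detections, tracks = trk,
              motion = mot, tortuosity = segmentTortuosity(tree))
    list(contrast = FrameStack(frames, px, fr, "contrast"),
         bmode = FrameStack(bframes, px, fr, "bmode"),
         groundTruth = gt)
  })
}

#' Render a 3D vessel tree as a micro-CT-like intensity volume
#'
#' Voxels whose center lies within the lumen radius of a centerline get
#' the vessel intensity, all others the background intensity; i.i.d.
#' Gaussian noise is added on top. Tubes are rendered as capless finite
#' cylinders per polyline edge with spheres at interior joints, so a
#' single straight vessel has the analytic cylinder volume. The exact
#' per-voxel tube radius is returned alongside as ground truth.
#'
#' @param tree a 3D [VesselTree-class].
#' @param voxelSizeUm isotropic voxel size in µm (default 26.5).
#' @param noiseSigma additive Gaussian noise sd (intensity units).
#' @param seed integer RNG seed (noise only).
#' @param vesselIntensity,backgroundIntensity intensity levels in `[0, 1]`.
#' @return list with `volume` ([Volume3D-class]) and `radius`
#'   ([RadiusMap-class], true tube radius in voxels).
#' @export
renderUctVolume <- function(tree, voxelSizeUm = 26.5, noiseSigma = 0,
                            seed = 1L, vesselIntensity = 0.8,
                            backgroundIntensity = 0.1) {
  if (voxelSizeUm <= 0) stop("'voxelSizeUm' must be > 0")
  bb <- boundingBox(tree)
  if (ncol(bb) != 3L) stop("'tree' must be 3D")
  lo <- bb[1L, ]; hi <- bb[2L, ]
  vs <- voxelSizeUm / 1000  # mm per voxel
  dims <- as.integer(ceiling((hi - lo) / vs))
  segrows <- NULL; joints <- NULL
  for (s in seq_along(segments(tree))) {
    p <- segments(tree)[[s]]
    rpx <- tree@radiusUm[s] / voxelSizeUm
    pv <- sweep(p, 2L, lo) / vs
    a <- pv[-nrow(pv), , drop = FALSE]; b <- pv[-1L, , drop = FALSE]
    segrows <- rbind(segrows, cbind(a, b, rpx))
    if (nrow(pv) > 2L)
      joints <- rbind(joints,
                      cbind(pv[2:(nrow(pv) - 1L), , drop = FALSE], rpx))
  }
  if (is.null(joints)) joints <- matrix(0, 0L, 4L)
  rf <- cpp_render_tubes(dims, segrows, joints)
  radius <- array(rf, dim = dims)
  vol <- array(backgroundIntensity, dim = dims)
  vol[radius > 0] <- vesselIntensity
  if (noiseSigma > 0)
    vol <- vol + withSeed(seed, array(stats::rnorm(prod(dims), 0, noiseSigma),
                                      dim = dims))
  list(volume = Volume3D(vol, voxelSizeUm),
       radius = new("RadiusMap", radius = radius, voxelSizeUm = voxelSizeUm))
}
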