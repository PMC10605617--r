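# Synthetic vascular tree generation with analytic ground truth.

#' Generate a synthetic branching vascular tree
#'
#' Builds a quasi-planar branching tree of polyline centerlines inside a
#' rectangular (2D) or box-shaped (3D) field of view. Root vessels enter
#' from the shallow edge and run towards depth, branching dichotomously;
#' each segment's centerline is a straight chord with an optional
#' sinusoidal perpendicular perturbation that raises its tortuosity in a
#' controlled, analytically known way. Vessel count (`nRootVessels`,
#' `branchingDepth`) controls density; `tortuosityAmp` controls
#' tortuosity. The generator is a pure function of its arguments,
#' including `seed`.
#'
#' With `tortuosityAmp = 0` every centerline is exactly straight
#' (distance-metric tortuosity 1). For a single full sine period of
#' amplitude \eqn{a} over a chord \eqn{L}, the tortuosity equals
#' \eqn{\frac{1}{L}\int_0^L \sqrt{1 + (2\pi a/L)^2 \cos^2(2\pi t/L)}\, dt},
#' which the polyline discretization reproduces to well under 1%.
#'
#' @param nRootVessels number of root vessels entering the field (>= 1).
#' @param branchingDepth number of dichotomous branching generations
#'   (0 = unbranched).
#' @param tortuosityAmp sinusoidal perturbation amplitude in mm (>= 0).
#' @param dims 2 or 3.
#' @param seed integer RNG seed.
#' @param boundingBox numeric `2 x dims` matrix (rows min/max, mm);
#'   defaults to a 12.8 mm square field in 2D and a 5 mm cube in 3D.
#' @param rootRadiusUm root lumen radius in µm (children shrink by 0.72
#'   per generation).
#' @param rootFlowSpeed root flow speed in mm/s (children slow by 0.8).
#' @param sinePeriods full sine periods per segment.
#' @param pointsPerSegment polyline sampling density.
#' @return A [VesselTree-class].
#' @examples
#' tr <- generateVesselTree(3, branchingDepth = 1, tortuosityAmp = 0.1,
#'                          seed = 7)
#' segmentTortuosity(tr)
#' @export
generateVesselTree <- function(nRootVessels, branchingDepth = 0L,
                               tortuosityAmp = 0, dims = 2L, seed = 1L,
                               boundingBox = NULL, rootRadiusUm = 150,
                               rootFlowSpeed = 10, sinePeriods = 1,
                               pointsPerSegment = 50L) {
  if (nRootVessels < 1L) stop("'nRootVessels' must be >= 1")
  if (branchingDepth < 0L) stop("'branchingDepth' must be >= 0")
  if (tortuosityAmp < 0) stop("'tortuosityAmp' must be >= 0")
  if (!dims %in% c(2L, 3L)) stop("'dims' must be 2 or 3")
  if (is.null(boundingBox)) {
    ext <- if (dims == 2L) 12.8 else 5
    boundingBox <- rbind(rep(0, dims), rep(ext, dims))
  }
  lo <- boundingBox[1L, ]; hi <- boundingBox[2L, ]
  H <- hi[2L] - lo[2L]

  withSeed(seed, {
    segs <- list(); rad <- numeric(); spd <- numeric()
    lab <- character(); par <- integer()
    # margin keeps the sine excursion and the lumen inside the box
    marg <- tortuosityAmp + rootRadiusUm / 1000 + 0.05

    clampPt <- function(p) pmin(pmax(p, lo + marg), hi - marg)

    makeSegment <- function(p0, ang, len) {
      # ang: direction angle in the x-z plane from +x towards +z
      dirv <- c(cos(ang), sin(ang))
      if (dims == 3L) dirv <- c(dirv, stats::runif(1, -0.15, 0.15))
      dirv <- dirv / sqrt(sum(dirv^2))
      p1 <- clampPt(p0 + len * dirv)
      tt <- seq(0, 1, length.out = pointsPerSegment)
      pts <- outer(rep(1, pointsPerSegment), p0) +
        outer(tt, p1 - p0)
      if (tortuosityAmp > 0) {
        nrm <- c(-dirv[2L], dirv[1L])          # in-plane perpendicular
        if (dims == 3L) nrm <- c(nrm, 0)
        nrm <- nrm / sqrt(sum(nrm^2))
        dev <- tortuosityAmp * sin(2 * pi * sinePeriods * tt)
        pts <- pts + outer(dev, nrm)
      }
      pts
    }

    regionOf <- function(pts) {
      zm <- mean(pts[, 2L])
      frac <- (zm - lo[2L]) / H
      if (frac < 1 / 3) "CO" else if (frac < 2 / 3) "OM" else "IM"
    }

    rootLen <- 0.62 * H
    x0s <- lo[1L] + (hi[1L] - lo[1L]) *
      (seq_len(nRootVessels) - 0.5) / nRootVessels
    frontier <- list()
    for (r in seq_len(nRootVessels)) {
      p0 <- c(x0s[r] + stats::runif(1, -0.2, 0.2), lo[2L] + marg)
      if (dims == 3L) p0 <- c(p0, mean(c(lo[3L], hi[3L])) +
                                stats::runif(1, -0.5, 0.5))
      p0 <- clampPt(p0)
      ang <- pi / 2 + stats::runif(1, -0.25, 0.25)
      pts <- makeSegment(p0, ang, rootLen)
      segs[[length(segs) + 1L]] <- pts
      rad <- c(rad, rootRadiusUm); spd <- c(spd, rootFlowSpeed)
      lab <- c(lab, regionOf(pts)); par <- c(par, 0L)
      frontier[[length(frontier) + 1L]] <-
        list(idx = length(segs), ang = ang, depth = 0L)
    }
    while (length(frontier)) {
      nd <- frontier[[1L]]; frontier <- frontier[-1L]
      if (nd$depth >= branchingDepth) next
      pts <- segs[[nd$idx]]
      tip <- pts[nrow(pts), ]
      len <- rootLen * 0.55^(nd$depth + 1L)
      for (side in c(-1, 1)) {
        ang <- nd$ang + side * stats::runif(1, 0.3, 0.6)
        cpts <- makeSegment(tip, ang, len)
        segs[[length(segs) + 1L]] <- cpts
        rad <- c(rad, rad[nd$idx] * 0.72)
        spd <- c(spd, spd[nd$idx] * 0.8)
        lab <- c(lab, regionOf(cpts)); par <- c(par, nd$idx)
        frontier[[length(frontier) + 1L]] <-
          list(idx = length(segs), ang = ang, depth = nd$depth + 1L)
      }
    }
    VesselTree(segs, rad, spd, lab, par, boundingBox)
  })
}

#' Ground-truth distance-metric tortuosity of each tree segment
#'
#' Arc length of the polyline centerline divided by its chord; exactly 1
#' for a straight segment.
#'
#' @param tree a [VesselTree-class].
#' @return numeric vector, one value >= 1 per segment.
#' @export
segmentTortuosity <- function(tree) {
  vapply(segments(tree), polylineTortuosity, numeric(1))
}

#' Keep a random subset of a tree's root lineages
#'
#' Emulates vascular rarefaction: whole root vessels (with all their
#' descendants) are removed at random until approximately `keep` of the
#' segments remain. Subsetting whole lineages preserves the connectivity
#' invariant that every child starts on its parent.
#'
#' @param tree a [VesselTree-class].
#' @param keep fraction of segments to retain, in (0, 1].
#' @param seed integer RNG seed.
#' @return A [VesselTree-class] with a subset of the segments.
#' @export
subsetVesselTree <- function(tree, keep, seed = 1L) {
  stopifnot(keep > 0, keep <= 1)
  par <- tree@parent
  ns <- length(tree@segments)
  root <- integer(ns)
  for (s in seq_len(ns)) root[s] <- if (par[s] == 0L) s else root[par[s]]
  roots <- which(par == 0L)
  withSeed(seed, {
    ord <- sample(roots)
    sizes <- vapply(ord, function(r) sum(root == r), integer(1))
    ntake <- which.min(abs(cumsum(sizes) - keep * ns))
    keptRoots <- ord[seq_len(ntake)]
  })
  sel <- which(root %in% keptRoots)
  remap <- integer(ns); remap[sel] <- seq_along(sel)
  pa <- par[sel]
  newpar <- integer(length(sel))
  newpar[pa > 0L] <- remap[pa[pa > 0L]]
  VesselTree(tree@segments[sel], tree@radiusUm[sel], tree@flowSpeed[sel],
             tree@regionLabel[sel], newpar, tree@boundingBox)
}

#' Band-shaped region-of-interest label mask on a raster grid
#'
#' Builds the label image used by the synthetic scenes: the field of view
#' is divided into three equal depth bands labeled `CO` (shallow), `OM`
#' and `IM` (deep), the same rule the tree generator uses to label its
#' segments.
#'
#' @param extent numeric(2): field width (x) and depth (z) in mm.
#' @param gridPixelSize raster pitch in mm.
#' @param origin numeric(2), physical (x, z) of the top-left corner in mm.
#' @return character matrix `[nz, nx]` with entries `"CO"`, `"OM"`, `"IM"`.
#' @export
regionBandMask <- function(extent, gridPixelSize = 0.025, origin = c(0, 0)) {
  nz <- ceiling(extent[2L] / gridPixelSize)
  nx <- ceiling(extent[1L] / gridPixelSize)
  zc <- (seq_len(nz) - 0.5) * gridPixelSize / extent[2L]
  lab <- ifelse(zc < 1 / 3, "CO", ifelse(zc < 2 / 3, "OM", "IM"))
  matrix(lab, nrow = nz, ncol = nx)
}

#' Ground-truth regional vessel density of a tree
#'
#' Rasterizes the tree onto a super-resolution grid and reports, per
#' region, the fraction of region pixels that are vessel pixels. In
#' `"centerline"` mode vessels are one supercover-pixel wide (the same
#' footprint a perfect track map would have); in `"lumen"` mode pixels
#' within the lumen radius of a centerline count as vessel. An
#' `"analytic"` mode instead sums segment arc length times lumen width
#' per region, ignoring vessel overlap.
#'
#' @param tree a 2D [VesselTree-class].
#' @param roi character label matrix (e.g. from [regionBandMask()]).
#' @param gridPixelSize raster pitch in mm.
#' @param mode `"centerline"`, `"lumen"` or `"analytic"`.
#' @return named numeric vector of per-region density fractions in `[0, 1]`.
#' @export
trueRegionDensity <- function(tree, roi, gridPixelSize = 0.025,
                              mode = c("centerline", "lumen", "analytic")) {
  mode <- match.arg(mode)
  bb <- boundingBox(tree)
  lo <- bb[1L, 1:2]; hi <- bb[2L, 1:2]
  regions <- c("CO", "OM", "IM")
  if (mode == "analytic") {
    ext <- hi - lo
    bandArea <- ext[1L] * ext[2L] / 3
    acc <- c(CO = 0, OM = 0, IM = 0)
    for (s in seq_along(segments(tree))) {
      p <- segments(tree)[[s]][, 1:2, drop = FALSE]
      w <- 2 * tree@radiusUm[s] / 1000
      a <- p[-nrow(p), , drop = FALSE]; b <- p[-1L, , drop = FALSE]
      len <- sqrt(rowSums((b - a)^2))
      zm <- (a[, 2L] + b[, 2L]) / 2
      fr <- (zm - lo[2L]) / ext[2L]
      band <- ifelse(fr < 1 / 3, "CO", ifelse(fr < 2 / 3, "OM", "IM"))
      for (g in regions) acc[g] <- acc[g] + sum(len[band == g]) * w
    }
    return(acc / bandArea)
  }
  nz <- nrow(roi); nx <- ncol(roi)
  if (mode == "centerline") {
    segsXY <- do.call(rbind, lapply(segments(tree), function(p) {
      p <- p[, 1:2, drop = FALSE]
      cbind(p[-nrow(p), , drop = FALSE], p[-1L, , drop = FALSE])
    }))
    r0 <- (segsXY[, 2L] - lo[2L]) / gridPixelSize
    c0 <- (segsXY[, 1L] - lo[1L]) / gridPixelSize
    r1 <- (segsXY[, 4L] - lo[2L]) / gridPixelSize
    c1 <- (segsXY[, 3L] - lo[1L]) / gridPixelSize
    ras <- cpp_raster_segments(r0, c0, r1, c1, nz, nx)
    fg <- ras$count > 0
  } else {
    segrows <- NULL; joints <- NULL
    for (s in seq_along(segments(tree))) {
      p <- segments(tree)[[s]][, 1:2, drop = FALSE]
      rpx <- tree@radiusUm[s] / 1000 / gridPixelSize
      a <- p[-nrow(p), , drop = FALSE]; b <- p[-1L, , drop = FALSE]
      segrows <- rbind(segrows, cbind(
        (a[, 2L] - lo[2L]) / gridPixelSize, (a[, 1L] - lo[1L]) / gridPixelSize,
        0.5,
        (b[, 2L] - lo[2L]) / gridPixelSize, (b[, 1L] - lo[1L]) / gridPixelSize,
        0.5, rpx))
      if (nrow(p) > 2L) {
        q <- p[2:(nrow(p) - 1L), , drop = FALSE]
        joints <- rbind(joints, cbind(
          (q[, 2L] - lo[2L]) / gridPixelSize,
          (q[, 1L] - lo[1L]) / gridPixelSize, 0.5, rpx))
      }
    }
    if (is.null(joints)) joints <- matrix(0, 0L, 4L)
    rf <- cpp_render_tubes(c(nz, nx, 1L), segrows, joints)
    fg <- matrix(rf > 0, nz, nx)
  }
  out <- vapply(regions, function(g) {
    inR <- roi == g
    if (!any(inR)) return(NA_real_)
    sum(fg & inR) / sum(inR)
  }, numeric(1))
  names(out) <- regions
  out
}
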