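# Super-resolved track accumulation, patch density and tortuosity.

#' Accumulate microbubble tracks into a super-resolved image
#'
#' Consecutive track points are joined by line segments rasterized with a
#' supercover traversal on the super-resolution grid: a pixel is
#' track-filled if any segment passes through it. The direction map
#' stores the per-pixel circular mean of the crossing segments' flow
#' angles (0 rad = flow towards +x; a reversed track maps to angle pi).
#' The default 25 µm grid keeps vessels below 75 µm resolvable.
#'
#' @param trackset a [TrackSet-class] (or a data.frame with `track_id`,
#'   `frame`, `x_mm`, `z_mm`).
#' @param gridPixelSize super-resolution pitch in mm (default 0.025).
#' @param extent numeric(2), field (x, z) size in mm.
#' @param origin numeric(2), physical (x, z) of the top-left corner (mm).
#' @return An [SRUSImage-class].
#' @export
accumulateTracks <- function(trackset, gridPixelSize = 0.025, extent,
                             origin = c(0, 0)) {
  stopifnot(gridPixelSize > 0)
  df <- if (is(trackset, "TrackSet")) tracks(trackset) else trackset
  nz <- ceiling(extent[2L] / gridPixelSize)
  nx <- ceiling(extent[1L] / gridPixelSize)
  if (nrow(df) < 2L) {
    ras <- matrix(FALSE, nz, nx)
    dir <- matrix(NA_real_, nz, nx)
    return(new("SRUSImage", raster = ras, direction = dir,
               pixelSize = gridPixelSize, origin = as.numeric(origin)))
  }
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  a <- df[-nrow(df), ]; b <- df[-1L, ]
  keep <- a$track_id == b$track_id
  a <- a[keep, ]; b <- b[keep, ]
  ras <- cpp_raster_segments(
    (a$z_mm - origin[2L]) / gridPixelSize,
    (a$x_mm - origin[1L]) / gridPixelSize,
    (b$z_mm - origin[2L]) / gridPixelSize,
    (b$x_mm - origin[1L]) / gridPixelSize, nz, nx)
  filled <- ras$count > 0
  dir <- matrix(NA_real_, nz, nx)
  dir[filled] <- atan2(ras$sumsin[filled], ras$sumcos[filled])
  new("SRUSImage", raster = filled, direction = dir,
      pixelSize = gridPixelSize, origin = as.numeric(origin))
}

#' Patch-based vascular density within a region of interest
#'
#' Square patches (default 2 x 2 mm², 50% overlap) are laid over the
#' region's bounding box with stride `patchSide * (1 - overlap)`,
#' anchored at the bounding box corner. A patch is evaluated only if at
#' least half of its pixels carry the region label; its density is the
#' fraction of the patch's region pixels that are track-filled, a value
#' from zero (no tracks) to one (patch completely covered by tracks).
#' The regional summary is the arithmetic mean over retained patches,
#' reported in percent.
#'
#' @param img an [SRUSImage-class].
#' @param roi character label matrix matching the raster (entries such
#'   as `"CO"`, `"OM"`, `"IM"`, `""`).
#' @param region label to quantify.
#' @param patchSide patch side in mm (default 2.0).
#' @param overlap patch overlap fraction in `[0, 1)` (default 0.5).
#' @param minRegionCover minimum fraction of region pixels for a patch
#'   to be retained (default 0.5).
#' @return list with `patches` (data.frame: `cx_mm`, `cz_mm`, `density`),
#'   `meanDensityPct`, `region`, `nPatches`.
#' @export
computePatchDensity <- function(img, roi, region, patchSide = 2.0,
                                overlap = 0.5, minRegionCover = 0.5) {
  stopifnot(patchSide > 0, overlap >= 0, overlap < 1)
  ras <- trackRaster(img)
  if (!identical(dim(roi), dim(ras)))
    stop("ROI mask shape does not match the SRUS raster")
  inR <- roi == region
  if (!any(inR)) stop(sprintf("region '%s' absent from the ROI mask", region))
  h <- pixelSize(img)
  side <- max(1L, round(patchSide / h))
  stride <- max(1L, round(side * (1 - overlap)))
  rows <- range(which(rowSums(inR) > 0))
  cols <- range(which(colSums(inR) > 0))
  i0s <- seq(rows[1L], max(rows[1L], rows[2L] - side + 1L), by = stride)
  j0s <- seq(cols[1L], max(cols[1L], cols[2L] - side + 1L), by = stride)
  res <- list()
  for (i0 in i0s) for (j0 in j0s) {
    i1 <- min(i0 + side - 1L, nrow(ras)); j1 <- min(j0 + side - 1L, ncol(ras))
    pr <- inR[i0:i1, j0:j1]
    if (mean(pr) < minRegionCover) next
    pf <- ras[i0:i1, j0:j1]
    res[[length(res) + 1L]] <- data.frame(
      cx_mm = gridOrigin(img)[1L] + (j0 + j1 - 1) / 2 * h,
      cz_mm = gridOrigin(img)[2L] + (i0 + i1 - 1) / 2 * h,
      density = sum(pf & pr) / sum(pr))
  }
  if (!length(res)) {
    warning(sprintf("no patch met the %.0f%% region-coverage rule",
                    100 * minRegionCover))
    return(list(patches = data.frame(cx_mm = numeric(), cz_mm = numeric(),
                                     density = numeric()),
                meanDensityPct = NA_real_, region = region, nPatches = 0L))
  }
  patches <- do.call(rbind, res)
  list(patches = patches, meanDensityPct = 100 * mean(patches$density),
       region = region, nPatches = nrow(patches))
}

#' Distance-metric tortuosity of microbubble tracks
#'
#' Per track: the actual path length (sum of Euclidean inter-point
#' distances) divided by the shortest distance from the start to the end
#' of the track. The value is 1 for a straight track and grows without
#' bound with meandering. A track is attributed to the region holding
#' the majority of its points (ties go to the first point's region);
#' tracks whose chord is shorter than the grid pitch (loop-like) are
#' excluded from the mean and tallied.
#'
#' @param trackset a [TrackSet-class] or long-form track data.frame.
#' @param roi character label matrix on the SRUS grid.
#' @param region region label; tracks assigned elsewhere are ignored.
#' @param gridPixelSize grid pitch in mm (chord-degeneracy cutoff).
#' @param origin physical (x, z) of the ROI raster's top-left corner (mm).
#' @return list with `perTrack` (data.frame: `track_id`, `tortuosity`),
#'   `meanTortuosity`, `region`, `nExcluded` (degenerate-chord count).
#' @export
computeTortuosity <- function(trackset, roi, region, gridPixelSize = 0.025,
                              origin = c(0, 0)) {
  df <- if (is(trackset, "TrackSet")) tracks(trackset) else trackset
  ids <- unique(df$track_id)
  vals <- data.frame(track_id = numeric(), tortuosity = numeric())
  nExcluded <- 0L
  nz <- nrow(roi); nx <- ncol(roi)
  for (id in ids) {
    p <- as.matrix(df[df$track_id == id, c("x_mm", "z_mm")])
    if (nrow(p) < 2L) next
    i <- pmin(pmax(ceiling((p[, 2L] - origin[2L]) / gridPixelSize), 1L), nz)
    j <- pmin(pmax(ceiling((p[, 1L] - origin[1L]) / gridPixelSize), 1L), nx)
    labs <- roi[cbind(i, j)]
    tab <- sort(table(labs), decreasing = TRUE)
    maj <- names(tab)[tab == max(tab)]
    lab <- if (length(maj) == 1L) maj else labs[1L]
    if (lab != region) next
    chord <- sqrt(sum((p[nrow(p), ] - p[1L, ])^2))
    if (chord < gridPixelSize) {
      nExcluded <- nExcluded + 1L
      next
    }
    vals <- rbind(vals, data.frame(track_id = id,
                                   tortuosity = polylineLength(p) / chord))
  }
  list(perTrack = vals,
       meanTortuosity = if (nrow(vals)) mean(vals$tortuosity) else NA_real_,
       region = region, nExcluded = nExcluded)
}

#' Sum-of-angles tortuosity (secondary metric)
#'
#' Total absolute turning angle along the track divided by its path
#' length (rad/mm). Provided for comparison with the literature; the
#' package's primary tortuosity read-out is the distance metric of
#' [computeTortuosity()].
#'
#' @param trackset a [TrackSet-class] or long-form track data.frame.
#' @return data.frame with `track_id` and `soam` (rad/mm).
#' @export
sumOfAnglesTortuosity <- function(trackset) {
  df <- if (is(trackset, "TrackSet")) tracks(trackset) else trackset
  ids <- unique(df$track_id)
  out <- lapply(ids, function(id) {
    p <- as.matrix(df[df$track_id == id, c("x_mm", "z_mm")])
    if (nrow(p) < 3L) return(NULL)
    v <- diff(p)
    len <- sqrt(rowSums(v^2))
    ok <- len > 0
    v <- v[ok, , drop = FALSE]; len <- len[ok]
    if (nrow(v) < 2L) return(NULL)
    ang <- atan2(v[, 2L], v[, 1L])
    dAng <- abs(atan2(sin(diff(ang)), cos(diff(ang))))
    data.frame(track_id = id, soam = sum(dAng) / sum(len))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(track_id = numeric(), soam = numeric()) else out
}
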