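# Micro-CT branch: kidney segmentation, label interpolation, vessel
# segmentation, local radius estimation and regional vessel density.

#' Segment the kidney by threshold-based region growing
#'
#' Grows a 26-connected region from a seed voxel over all voxels with
#' intensity at or above the threshold, then applies a morphological
#' closing with a Euclidean ball (default radius 2 voxels) to smooth
#' small openings such as the hilum.
#'
#' @param vol a [Volume3D-class].
#' @param seedPoint integer(3), 1-based voxel index inside the organ.
#' @param threshold intensity threshold; the seed must be at or above it.
#' @param closingRadius ball radius in voxels for the smoothing closing.
#' @return logical 3D mask.
#' @export
segmentKidney <- function(vol, seedPoint, threshold, closingRadius = 2) {
  d <- dim(volumeData(vol))
  seedPoint <- as.integer(seedPoint)
  if (any(seedPoint < 1L) || any(seedPoint > d))
    stop("seed point outside the volume")
  if (threshold > max(volumeData(vol)))
    stop("threshold exceeds the volume's maximum intensity")
  if (volumeData(vol)[seedPoint[1L], seedPoint[2L], seedPoint[3L]] < threshold)
    stop("seed voxel intensity is below the threshold")
  grown <- cpp_flood26(as.numeric(volumeData(vol)), d, seedPoint - 1L,
                       threshold)
  mask <- array(grown, dim = d)
  binaryClose(mask, closingRadius)
}

#' Densify sparse slice labels by signed-distance interpolation
#'
#' Shape-based interpolation: per label, each labeled slice is converted
#' to a 2D signed distance field (positive inside), the fields of the two
#' nearest labeled slices are linearly interpolated along the slice axis,
#' and the result is thresholded at zero. Labeled slices are reproduced
#' exactly; slices outside the labeled range replicate the nearest
#' labeled slice. With a single labeled slice the label is replicated
#' throughout, with a warning. Where several labels claim a voxel the
#' one with the largest interpolated signed distance wins.
#'
#' @param labels integer 3D array; 0 = unlabeled, slices along `axis`
#'   are either entirely 0 (to be filled) or carry the sparse labels.
#' @param labeledSlices indices of the annotated slices; by default,
#'   slices containing any non-zero voxel.
#' @param axis slice axis (default 3).
#' @return integer 3D array with every slice labeled.
#' @export
interpolateLabels <- function(labels, labeledSlices = NULL, axis = 3L) {
  d <- dim(labels)
  stopifnot(length(d) == 3L)
  perm <- switch(as.integer(axis), c(3L, 1L, 2L), c(1L, 3L, 2L), c(1L, 2L, 3L))
  lab <- aperm(labels, perm)
  d3 <- dim(lab)[3L]
  if (is.null(labeledSlices))
    labeledSlices <- which(apply(lab != 0, 3L, any))
  labeledSlices <- sort(unique(as.integer(labeledSlices)))
  if (length(labeledSlices) == 0L) stop("no labeled slices found")
  vals <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (length(labeledSlices) == 1L)
    warning("single labeled slice: replicating it across the volume")

  sdfSlice <- function(sl, v) {
    m <- sl == v
    # positive inside the label, negative outside (center distances)
    euclideanDistance(m) - euclideanDistance(!m)
  }
  out <- array(0L, dim = dim(lab))
  bestSdf <- array(-Inf, dim = dim(lab))
  for (v in vals) {
    sdfs <- lapply(labeledSlices, function(k) sdfSlice(lab[, , k], v))
    for (k in seq_len(d3)) {
      pos <- findInterval(k, labeledSlices)
      s <- if (pos == 0L) sdfs[[1L]]
      else if (pos >= length(labeledSlices)) sdfs[[length(sdfs)]]
      else {
        k0 <- labeledSlices[pos]; k1 <- labeledSlices[pos + 1L]
        w <- (k - k0) / (k1 - k0)
        (1 - w) * sdfs[[pos]] + w * sdfs[[pos + 1L]]
      }
      upd <- s > 0 & s > bestSdf[, , k]
      if (any(upd)) {
        sl <- out[, , k]; bs <- bestSdf[, , k]
        sl[upd] <- v; bs[upd] <- s[upd]
        out[, , k] <- sl; bestSdf[, , k] <- bs
      }
    }
  }
  # annotated slices are authoritative
  for (k in labeledSlices) out[, , k] <- lab[, , k]
  aperm(out, order(perm))
}

#' Threshold-based vessel segmentation within an organ mask
#'
#' The threshold is a required explicit input: it mirrors a per-scan
#' manual tuning step (low enough not to lose vessels, high enough not
#' to bridge the tissue between them).
#'
#' @param vol a [Volume3D-class].
#' @param mask logical organ mask (same shape).
#' @param threshold intensity threshold.
#' @return logical vessel mask, `(vol >= threshold) & mask`.
#' @export
segmentVessels <- function(vol, mask, threshold) {
  v <- volumeData(vol)
  stopifnot(identical(dim(v), dim(mask)))
  rng <- range(v)
  if (threshold < rng[1L] || threshold > rng[2L])
    warning("threshold lies outside the volume's intensity range")
  (v >= threshold) & mask
}

#' Local vessel radius by maximal inscribed spheres
#'
#' For every vessel voxel, the radius (in voxels) of the largest sphere
#' that fits entirely inside the vessel segmentation and contains that
#' voxel (local thickness). Computed as a Euclidean distance transform
#' followed by sphere propagation: every foreground voxel's
#' distance-to-background sphere paints its radius over the voxels it
#' covers, and each voxel keeps the largest radius painted onto it. An
#' isolated voxel gets its distance-transform value of 1 voxel.
#'
#' @param vesselMask logical 3D array.
#' @param voxelSizeUm voxel size in µm, carried into the result.
#' @return A [RadiusMap-class] (radii in voxels; 0 outside the mask).
#' @export
estimateLocalRadius <- function(vesselMask, voxelSizeUm = 26.5) {
  d <- dim(vesselMask)
  stopifnot(length(d) == 3L)
  if (!any(vesselMask))
    return(new("RadiusMap", radius = array(0, dim = d),
               voxelSizeUm = voxelSizeUm))
  dt <- sqrt(cpp_edt_sq(as.logical(vesselMask), as.integer(d)))
  lt <- cpp_local_thickness(dt, as.integer(d))
  new("RadiusMap", radius = array(lt, dim = d), voxelSizeUm = voxelSizeUm)
}

#' Split a vessel segmentation into small and large vessels
#'
#' Thresholds the local radius map: voxels with `0 < radius < threshold`
#' form the small-vessel mask, voxels with `radius >= threshold` the
#' large-vessel mask. The two masks partition the vessel segmentation
#' exactly. Thresholds of 10 voxels (cortex) and 6 voxels (medulla)
#' separate the renal artery/vein, segmental and arcuate vessels from
#' the microvasculature at 26.5 µm voxels.
#'
#' @param rmap a [RadiusMap-class].
#' @param threshold radius threshold in voxels (> 0).
#' @return list with logical arrays `small` and `large`.
#' @export
partitionByRadius <- function(rmap, threshold) {
  stopifnot(threshold > 0)
  r <- radiusField(rmap)
  list(small = r > 0 & r < threshold, large = r >= threshold)
}

#' Small-vessel volume density of a region
#'
#' Density = (small-vessel voxels inside the region) divided by (region
#' voxels after removing large-vessel voxels). Removing the large
#' vessels from both numerator and denominator makes the read-out the
#' small-vessel fraction of the remaining tissue.
#'
#' @param small,large logical vessel masks from [partitionByRadius()].
#' @param region logical region mask (same shape).
#' @param regionLabel label carried into the result.
#' @param radiusThreshold threshold (voxels) carried into the result.
#' @return data.frame with `region`, `small_voxels`, `region_voxels`
#'   (after large-vessel removal), `density` (fraction) and
#'   `radius_threshold_vox`.
#' @export
computeRegionDensity <- function(small, large, region, regionLabel = "",
                                 radiusThreshold = NA_real_) {
  stopifnot(identical(dim(small), dim(region)),
            identical(dim(large), dim(region)))
  denom <- sum(region & !large)
  if (denom == 0L) stop("region is empty after large-vessel removal")
  num <- sum(small & region)
  data.frame(region = regionLabel, small_voxels = num,
             region_voxels = denom, density = num / denom,
             radius_threshold_vox = radiusThreshold)
}
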