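#' @useDynLib ulmvasc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# ---------------------------------------------------------------------------
# FrameStack
# ---------------------------------------------------------------------------

#' Time-ordered stack of 2D ultrasound frames
#'
#' A `FrameStack` holds an ordered sequence of 2D intensity images with
#' physical calibration: the isotropic pixel size in mm and the frame rate
#' in Hz. Frames are stored as a 3D array `[z, x, t]` (rows are depth,
#' columns are lateral position). `kind` distinguishes contrast-mode stacks
#' (microbubble signal) from the interleaved B-mode stacks used for
#' speckle-tracking motion estimation.
#'
#' @slot frames numeric 3D array `[nz, nx, nFrames]`, intensities in `[0, 1]`.
#' @slot pixelSize numeric(1), pixel side in mm.
#' @slot frameRate numeric(1), frames per second (Hz).
#' @slot kind `"contrast"` or `"bmode"`.
#'
#' @exportClass FrameStack
setClass("FrameStack",
  representation(frames = "array", pixelSize = "numeric",
                 frameRate = "numeric", kind = "character"))

setValidity("FrameStack", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "'frames' must be a 3D array [z, x, t]")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "'pixelSize' must be a single positive number (mm)")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    msg <- c(msg, "'frameRate' must be a single positive number (Hz)")
  if (!object@kind %in% c("contrast", "bmode"))
    msg <- c(msg, "'kind' must be \"contrast\" or \"bmode\"")
  if (length(msg)) msg else TRUE
})

#' @param frames numeric 3D array `[nz, nx, nFrames]`.
#' @param pixelSize pixel side in mm.
#' @param frameRate frame rate in Hz.
#' @param kind `"contrast"` or `"bmode"`.
#' @return A [FrameStack-class] object.
#' @rdname FrameStack-class
#' @export
FrameStack <- function(frames, pixelSize, frameRate, kind = "contrast") {
  new("FrameStack", frames = frames, pixelSize = as.numeric(pixelSize),
      frameRate = as.numeric(frameRate), kind = kind)
}

# ---------------------------------------------------------------------------
# VesselTree
# ---------------------------------------------------------------------------

#' Synthetic branching vascular tree with known geometry
#'
#' Ground-truth vascular geometry for simulation: a list of polyline
#' centerlines (2D or 3D, coordinates in mm) with per-segment radius,
#' signed flow speed along the polyline, anatomical region label and
#' parent linkage (children start on a point of their parent's polyline).
#'
#' @slot segments list of numeric matrices, one per segment; each row a
#'   centerline point (mm), 2 or 3 columns (`x`, `z`\[, `y`\]).
#' @slot radiusUm numeric, per-segment lumen radius in µm.
#' @slot flowSpeed numeric, per-segment flow speed in mm/s, signed along
#'   the polyline orientation.
#' @slot regionLabel character, per-segment label in
#'   `c("CO", "OM", "IM", "")` (cortex, outer/inner medulla, unlabeled).
#' @slot parent integer, per-segment parent index (0 for roots).
#' @slot boundingBox numeric matrix `2 x ndim`, rows `min`/`max` in mm.
#'
#' @exportClass VesselTree
setClass("VesselTree",
  representation(segments = "list", radiusUm = "numeric",
                 flowSpeed = "numeric", regionLabel = "character",
                 parent = "integer", boundingBox = "matrix"))

setValidity("VesselTree", function(object) {
  ns <- length(object@segments)
  msg <- character()
  if (ns == 0L) msg <- c(msg, "tree has no segments")
  if (length(object@radiusUm) != ns || length(object@flowSpeed) != ns ||
      length(object@regionLabel) != ns || length(object@parent) != ns)
    return("per-segment slots must all have one entry per segment")
  if (any(object@radiusUm <= 0)) msg <- c(msg, "all radii must be > 0")
  if (!all(object@regionLabel %in% c("CO", "OM", "IM", "")))
    msg <- c(msg, "region labels must be CO, OM, IM or \"\"")
  nd <- ncol(object@boundingBox)
  for (s in seq_len(ns)) {
    p <- object@segments[[s]]
    if (!is.matrix(p) || nrow(p) < 2L || ncol(p) != nd)
      return(sprintf("segment %d: polyline needs >= 2 points with %d coords", s, nd))
    lo <- object@boundingBox[1L, ]; hi <- object@boundingBox[2L, ]
    if (any(t(p) < lo - 1e-9) || any(t(p) > hi + 1e-9))
      msg <- c(msg, sprintf("segment %d leaves the bounding box", s))
    pa <- object@parent[s]
    if (pa > 0L) {
      pp <- object@segments[[pa]]
      d2 <- colSums((t(pp) - p[1L, ])^2)
      if (min(d2) > 1e-12)
        msg <- c(msg, sprintf("segment %d does not start on its parent", s))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param segments,radiusUm,flowSpeed,regionLabel,parent,boundingBox see slots.
#' @return A [VesselTree-class] object.
#' @rdname VesselTree-class
#' @export
VesselTree <- function(segments, radiusUm, flowSpeed, regionLabel, parent,
                       boundingBox) {
  new("VesselTree", segments = segments, radiusUm = as.numeric(radiusUm),
      flowSpeed = as.numeric(flowSpeed), regionLabel = as.character(regionLabel),
      parent = as.integer(parent), boundingBox = boundingBox)
}

# ---------------------------------------------------------------------------
# GroundTruth
# ---------------------------------------------------------------------------

#' Ground truth emitted alongside a simulated microbubble movie
#'
#' Records what the simulator actually did so downstream stages can be
#' scored: the exact sub-pixel bubble positions per frame, the per-bubble
#' trajectories, the injected tissue displacement per frame, and the
#' per-segment tortuosity of the generating tree.
#'
#' @slot detections data.frame with columns `frame`, `x_mm`, `z_mm`,
#'   `bubble_id` (positions before tissue motion is applied).
#' @slot tracks data.frame with columns `bubble_id`, `frame`, `x_mm`, `z_mm`.
#' @slot motion numeric matrix `nFrames x 2` (`dx`, `dz` in mm), the rigid
#'   displacement applied to every frame.
#' @slot tortuosity numeric, per-segment distance-metric tortuosity of the
#'   generating tree (>= 1).
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(detections = "data.frame", tracks = "data.frame",
                 motion = "matrix", tortuosity = "numeric"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!all(c("frame", "x_mm", "z_mm", "bubble_id") %in% names(object@detections)))
    msg <- c(msg, "'detections' needs columns frame, x_mm, z_mm, bubble_id")
  if (!all(c("bubble_id", "frame", "x_mm", "z_mm") %in% names(object@tracks)))
    msg <- c(msg, "'tracks' needs columns bubble_id, frame, x_mm, z_mm")
  if (ncol(object@motion) != 2L) msg <- c(msg, "'motion' must be n x 2")
  if (length(object@tortuosity) && any(object@tortuosity < 1 - 1e-9))
    msg <- c(msg, "tortuosity must be >= 1")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# MotionField
# ---------------------------------------------------------------------------

#' Per-frame rigid displacement relative to a reference frame
#'
#' @slot displacement numeric matrix `nFrames x 2`, columns `dx`, `dz` (mm):
#'   the estimated displacement of each frame's tissue relative to the
#'   reference frame. The row at `referenceIndex` is exactly `(0, 0)`.
#' @slot referenceIndex integer(1), 1-based reference frame.
#' @slot confidence numeric, per-frame peak normalized cross-correlation
#'   (values below 0.5 flag unreliable estimates).
#'
#' @exportClass MotionField
setClass("MotionField",
  representation(displacement = "matrix", referenceIndex = "integer",
                 confidence = "numeric"))

setValidity("MotionField", function(object) {
  msg <- character()
  if (ncol(object@displacement) != 2L)
    msg <- c(msg, "'displacement' must have two columns (dx, dz)")
  ri <- object@referenceIndex
  if (length(ri) != 1L || ri < 1L || ri > nrow(object@displacement))
    msg <- c(msg, "'referenceIndex' out of range")
  else if (any(object@displacement[ri, ] != 0))
    msg <- c(msg, "displacement at the reference frame must be (0, 0)")
  if (length(object@confidence) != nrow(object@displacement))
    msg <- c(msg, "'confidence' must have one entry per frame")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# TrackSet
# ---------------------------------------------------------------------------

#' A set of linked microbubble trajectories
#'
#' Tracks are stored long-form: one row per (track, frame) observation,
#' ordered by track then frame. Within each track the frame indices are
#' strictly consecutive (the linker tolerates no gaps) — a bubble missed
#' for one frame terminates its track.
#'
#' @slot tracks data.frame with columns `track_id`, `frame`, `x_mm`, `z_mm`.
#' @slot frameRate numeric(1) Hz, carried along for velocity-based analyses.
#'
#' @exportClass TrackSet
setClass("TrackSet",
  representation(tracks = "data.frame", frameRate = "numeric"))

setValidity("TrackSet", function(object) {
  df <- object@tracks
  if (!all(c("track_id", "frame", "x_mm", "z_mm") %in% names(df)))
    return("'tracks' needs columns track_id, frame, x_mm, z_mm")
  if (nrow(df)) {
    byid <- split(df$frame, df$track_id)
    ok <- vapply(byid, function(f) all(diff(f) == 1L), logical(1))
    if (!all(ok))
      return("every track must span strictly consecutive frames")
  }
  TRUE
})

#' @param tracks long-form data.frame (`track_id`, `frame`, `x_mm`, `z_mm`).
#' @param frameRate acquisition frame rate in Hz.
#' @return A [TrackSet-class] object.
#' @rdname TrackSet-class
#' @export
TrackSet <- function(tracks, frameRate) {
  if (nrow(tracks))
    tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  new("TrackSet", tracks = tracks, frameRate = as.numeric(frameRate))
}

# ---------------------------------------------------------------------------
# SRUSImage
# ---------------------------------------------------------------------------

#' Super-resolved vascular map accumulated from microbubble tracks
#'
#' @slot raster logical matrix `[nz, nx]` on the super-resolution grid;
#'   `TRUE` where at least one track segment crosses the pixel.
#' @slot direction numeric matrix, per-pixel circular-mean flow angle in
#'   radians (angle 0 = +x direction, measured towards +z); `NA` on pixels
#'   no track crosses.
#' @slot pixelSize numeric(1), super-resolution grid pitch in mm.
#' @slot origin numeric(2), physical coordinate (x, z) in mm of the
#'   raster's top-left pixel corner.
#'
#' @exportClass SRUSImage
setClass("SRUSImage",
  representation(raster = "matrix", direction = "matrix",
                 pixelSize = "numeric", origin = "numeric"))

setValidity("SRUSImage", function(object) {
  msg <- character()
  if (!identical(dim(object@raster), dim(object@direction)))
    msg <- c(msg, "raster and direction map must have the same shape")
  if (object@pixelSize <= 0) msg <- c(msg, "'pixelSize' must be > 0")
  if (length(object@origin) != 2L) msg <- c(msg, "'origin' must be (x, z)")
  if (any(!is.na(object@direction[!object@raster])))
    msg <- c(msg, "direction must be NA outside track-filled pixels")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Volume3D / RadiusMap / RegionMasks3D
# ---------------------------------------------------------------------------

#' 3D intensity volume with isotropic voxel size
#'
#' @slot data numeric 3D array.
#' @slot voxelSizeUm numeric(1), isotropic voxel side in µm (26.5 µm for
#'   the micro-CT protocol this mirrors).
#'
#' @exportClass Volume3D
setClass("Volume3D",
  representation(data = "array", voxelSizeUm = "numeric"))

setValidity("Volume3D", function(object) {
  if (length(dim(object@data)) != 3L) return("'data' must be a 3D array")
  if (length(object@voxelSizeUm) != 1L || object@voxelSizeUm <= 0)
    return("'voxelSizeUm' must be a single positive number")
  TRUE
})

#' @param data 3D numeric array.
#' @param voxelSizeUm isotropic voxel side in µm.
#' @return A [Volume3D-class] object.
#' @rdname Volume3D-class
#' @export
Volume3D <- function(data, voxelSizeUm = 26.5) {
  new("Volume3D", data = data, voxelSizeUm = as.numeric(voxelSizeUm))
}

#' Local vessel radius field over a binary segmentation
#'
#' Per-voxel local radius in voxel units: the radius of the largest sphere
#' that fits entirely inside the vessel segmentation and contains the
#' voxel (maximal inscribed sphere / local thickness). Exactly the
#' segmented voxels carry a positive radius.
#'
#' @slot radius numeric 3D array, radius in voxels; 0 outside the mask.
#' @slot voxelSizeUm numeric(1), voxel side in µm (converts to physical radii).
#'
#' @exportClass RadiusMap
setClass("RadiusMap",
  representation(radius = "array", voxelSizeUm = "numeric"))

setValidity("RadiusMap", function(object) {
  if (length(dim(object@radius)) != 3L) return("'radius' must be a 3D array")
  if (any(object@radius < 0)) return("radii must be >= 0")
  TRUE
})

#' Kidney / medulla / cortex masks with exact set relations
#'
#' The cortex is defined as the exact set difference kidney minus medulla,
#' mirroring an anatomical workflow in which the medulla is delineated
#' at the arcuate vessels and 'subtracted' from the whole-kidney mask.
#'
#' @slot kidney,medulla,cortex logical 3D arrays of identical shape.
#'
#' @exportClass RegionMasks3D
setClass("RegionMasks3D",
  representation(kidney = "array", medulla = "array", cortex = "array"))

setValidity("RegionMasks3D", function(object) {
  if (!identical(dim(object@kidney), dim(object@medulla)) ||
      !identical(dim(object@kidney), dim(object@cortex)))
    return("all masks must have the same shape")
  if (any(object@medulla & !object@kidney))
    return("medulla must be a subset of kidney")
  if (!identical(as.vector(object@cortex),
                 as.vector(object@kidney & !object@medulla)))
    return("cortex must equal kidney minus medulla exactly")
  TRUE
})

#' @param kidney,medulla logical 3D arrays; the cortex is derived as
#'   `kidney & !medulla`.
#' @return A [RegionMasks3D-class] object.
#' @rdname RegionMasks3D-class
#' @export
RegionMasks3D <- function(kidney, medulla) {
  new("RegionMasks3D", kidney = kidney, medulla = medulla,
      cortex = kidney & !medulla)
}

# ---------------------------------------------------------------------------
# Parameter objects
# ---------------------------------------------------------------------------

#' Acquisition parameters for the microbubble movie simulator
#'
#' Defaults mirror the contrast-mode protocol the pipeline targets: 55 Hz
#' frame rate with interleaved B-mode, a 10 MHz center frequency at
#' mechanical index 0.1 (recorded as metadata only — the point-spread
#' function is modeled as an isotropic Gaussian, not simulated acoustics),
#' continuous microbubble influx, and slow ventilation-like sinusoidal
#' tissue motion.
#'
#' @slot frameRate Hz.
#' @slot nFrames number of contrast frames.
#' @slot pixelSize mm, isotropic.
#' @slot psfSigma mm, Gaussian point-spread standard deviation.
#' @slot mbInfluxRate bubbles/s entering the whole field of view (Poisson).
#' @slot noiseSigma additive Gaussian noise standard deviation
#'   (intensities are on an arbitrary `[0, 1]` scale).
#' @slot motionAmplitude mm, peak rigid tissue displacement.
#' @slot motionPeriod s, period of the sinusoidal motion.
#' @slot motionAngleDeg direction of the motion vector, degrees from +x
#'   towards +z (90 = purely axial).
#' @slot minEntryGap s, minimum spacing between bubbles entering the
#'   same vessel (hard-core thinning of the Poisson entries). Microvessels
#'   carry bubbles in single file, so two bubbles co-advecting within one
#'   point-spread width would be unphysical as well as unresolvable; 0
#'   disables the thinning and gives pure Poisson influx.
#' @slot centerFrequencyMHz,mechanicalIndex acquisition metadata (not used
#'   by the simulator physics).
#' @slot seed integer RNG seed; simulation is a pure function of
#'   (tree, params).
#'
#' @exportClass AcquisitionParams
setClass("AcquisitionParams",
  representation(frameRate = "numeric", nFrames = "integer",
                 pixelSize = "numeric", psfSigma = "numeric",
                 mbInfluxRate = "numeric", noiseSigma = "numeric",
                 motionAmplitude = "numeric", motionPeriod = "numeric",
                 motionAngleDeg = "numeric", minEntryGap = "numeric",
                 centerFrequencyMHz = "numeric",
                 mechanicalIndex = "numeric", seed = "integer"),
  prototype(frameRate = 55, nFrames = 550L, pixelSize = 0.05,
            psfSigma = 0.15, mbInfluxRate = 8, noiseSigma = 0.02,
            motionAmplitude = 0.2, motionPeriod = 1.2, motionAngleDeg = 70,
            minEntryGap = 0.1, centerFrequencyMHz = 10,
            mechanicalIndex = 0.1, seed = 1L))

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (object@frameRate <= 0) msg <- c(msg, "'frameRate' must be > 0")
  if (object@nFrames < 1L) msg <- c(msg, "'nFrames' must be >= 1")
  if (object@pixelSize <= 0) msg <- c(msg, "'pixelSize' must be > 0")
  if (object@psfSigma <= 0) msg <- c(msg, "'psfSigma' must be > 0")
  if (object@mbInfluxRate < 0) msg <- c(msg, "'mbInfluxRate' must be >= 0")
  if (object@noiseSigma < 0) msg <- c(msg, "'noiseSigma' must be >= 0")
  if (object@motionAmplitude < 0) msg <- c(msg, "'motionAmplitude' must be >= 0")
  if (object@motionPeriod <= 0) msg <- c(msg, "'motionPeriod' must be > 0")
  if (object@minEntryGap < 0) msg <- c(msg, "'minEntryGap' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param ... slot overrides, e.g. `acquisitionParams(nFrames = 200L)`.
#' @return An [AcquisitionParams-class] object.
#' @rdname AcquisitionParams-class
#' @export
acquisitionParams <- function(...) {
  args <- list(...)
  for (nm in c("nFrames", "seed"))
    if (nm %in% names(args)) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c("AcquisitionParams", args))
}

#' Parameters of the hierarchical Kalman microbubble linker
#'
#' @slot maxLinkDistance mm, assignment gate between a track's predicted
#'   position and a candidate detection. `NA` (the default) derives the
#'   gate as `maxSpeed / frameRate` at tracking time.
#' @slot maxSpeed mm/s, fastest flow the linker should follow (used only
#'   to derive the default gate).
#' @slot processNoise (mm/s^2)^2, white-acceleration spectral density of
#'   the constant-velocity model.
#' @slot measurementNoise mm^2, localization error variance.
#' @slot minTrackLength frames; trajectories observed in fewer consecutive
#'   frames are discarded (default 3).
#' @slot nHierarchyPasses number of linking passes; later passes re-link
#'   the detections left over by earlier passes with a widened gate.
#' @slot passGateScale gate multiplier applied at each successive pass.
#'
#' @exportClass TrackerParams
setClass("TrackerParams",
  representation(maxLinkDistance = "numeric", maxSpeed = "numeric",
                 processNoise = "numeric", measurementNoise = "numeric",
                 minTrackLength = "integer", nHierarchyPasses = "integer",
                 passGateScale = "numeric"),
  prototype(maxLinkDistance = NA_real_, maxSpeed = 20, processNoise = 1,
            measurementNoise = 1e-4, minTrackLength = 3L,
            nHierarchyPasses = 2L, passGateScale = 2))

setValidity("TrackerParams", function(object) {
  msg <- character()
  if (!is.na(object@maxLinkDistance) && object@maxLinkDistance <= 0)
    msg <- c(msg, "'maxLinkDistance' must be > 0")
  if (object@maxSpeed <= 0) msg <- c(msg, "'maxSpeed' must be > 0")
  if (object@processNoise <= 0 || object@measurementNoise <= 0)
    msg <- c(msg, "noise variances must be > 0")
  if (object@minTrackLength < 1L) msg <- c(msg, "'minTrackLength' must be >= 1")
  if (object@nHierarchyPasses < 1L) msg <- c(msg, "'nHierarchyPasses' must be >= 1")
  if (object@passGateScale <= 0) msg <- c(msg, "'passGateScale' must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param ... slot overrides, e.g. `trackerParams(minTrackLength = 3L)`.
#' @return A [TrackerParams-class] object.
#' @rdname TrackerParams-class
#' @export
trackerParams <- function(...) {
  args <- list(...)
  for (nm in c("minTrackLength", "nHierarchyPasses"))
    if (nm %in% names(args)) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c("TrackerParams", args))
}
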