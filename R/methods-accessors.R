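# Accessor and show() methods.

#' @rdname ulmvasc-accessors
setMethod("frames", "FrameStack", function(object) object@frames)
#' @rdname ulmvasc-accessors
setMethod("pixelSize", "FrameStack", function(object) object@pixelSize)
#' @rdname ulmvasc-accessors
setMethod("pixelSize", "SRUSImage", function(object) object@pixelSize)
#' @rdname ulmvasc-accessors
setMethod("frameRate", "FrameStack", function(object) object@frameRate)
#' @rdname ulmvasc-accessors
setMethod("frameRate", "TrackSet", function(object) object@frameRate)
#' @rdname ulmvasc-accessors
setMethod("nFrames", "FrameStack", function(object) dim(object@frames)[3L])
#' @rdname ulmvasc-accessors
setMethod("stackKind", "FrameStack", function(object) object@kind)

#' @rdname ulmvasc-accessors
setMethod("segments", "VesselTree", function(object) object@segments)
#' @rdname ulmvasc-accessors
setMethod("segmentRadii", "VesselTree", function(object) object@radiusUm)
#' @rdname ulmvasc-accessors
setMethod("flowSpeeds", "VesselTree", function(object) object@flowSpeed)
#' @rdname ulmvasc-accessors
setMethod("regionLabels", "VesselTree", function(object) object@regionLabel)
#' @rdname ulmvasc-accessors
setMethod("boundingBox", "VesselTree", function(object) object@boundingBox)

#' @rdname ulmvasc-accessors
setMethod("displacement", "MotionField", function(object) object@displacement)
#' @rdname ulmvasc-accessors
setMethod("referenceIndex", "MotionField", function(object) object@referenceIndex)
#' @rdname ulmvasc-accessors
setMethod("motionConfidence", "MotionField", function(object) object@confidence)

#' @rdname ulmvasc-accessors
setMethod("tracks", "TrackSet", function(object) object@tracks)
#' @rdname ulmvasc-accessors
setMethod("nTracks", "TrackSet",
          function(object) length(unique(object@tracks$track_id)))

#' @rdname ulmvasc-accessors
setMethod("trackRaster", "SRUSImage", function(object) object@raster)
#' @rdname ulmvasc-accessors
setMethod("directionMap", "SRUSImage", function(object) object@direction)
#' @rdname ulmvasc-accessors
setMethod("gridOrigin", "SRUSImage", function(object) object@origin)

#' @rdname ulmvasc-accessors
setMethod("voxelSize", "Volume3D", function(object) object@voxelSizeUm)
#' @rdname ulmvasc-accessors
setMethod("voxelSize", "RadiusMap", function(object) object@voxelSizeUm)
#' @rdname ulmvasc-accessors
setMethod("volumeData", "Volume3D", function(object) object@data)
#' @rdname ulmvasc-accessors
setMethod("radiusField", "RadiusMap", function(object) object@radius)

#' @rdname ulmvasc-accessors
setMethod("kidneyMask", "RegionMasks3D", function(object) object@kidney)
#' @rdname ulmvasc-accessors
setMethod("medullaMask", "RegionMasks3D", function(object) object@medulla)
#' @rdname ulmvasc-accessors
setMethod("cortexMask", "RegionMasks3D", function(object) object@cortex)

#' @rdname ulmvasc-accessors
setMethod("trueDetections", "GroundTruth", function(object) object@detections)
#' @rdname ulmvasc-accessors
setMethod("trueTracks", "GroundTruth", function(object) object@tracks)
#' @rdname ulmvasc-accessors
setMethod("trueMotion", "GroundTruth", function(object) object@motion)
#' @rdname ulmvasc-accessors
setMethod("trueTortuosity", "GroundTruth", function(object) object@tortuosity)

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack (%s): %d frames of %d x %d px, %.3g mm/px, %.3g Hz\n",
              object@kind, d[3L], d[1L], d[2L], object@pixelSize,
              object@frameRate))
})

setMethod("show", "VesselTree", function(object) {
  nd <- ncol(object@boundingBox)
  lab <- object@regionLabel
  cat(sprintf("VesselTree: %d segments (%dD), radii %.0f-%.0f um\n",
              length(object@segments), nd, min(object@radiusUm),
              max(object@radiusUm)))
  cat(sprintf("  regions: CO=%d OM=%d IM=%d unlabeled=%d\n",
              sum(lab == "CO"), sum(lab == "OM"), sum(lab == "IM"),
              sum(lab == "")))
})

setMethod("show", "MotionField", function(object) {
  mx <- max(abs(object@displacement))
  cat(sprintf(
    "MotionField: %d frames, reference %d, max |displacement| %.3g mm, min confidence %.2f\n",
    nrow(object@displacement), object@referenceIndex, mx,
    min(object@confidence)))
})

setMethod("show", "TrackSet", function(object) {
  n <- nTracks(object)
  cat(sprintf("TrackSet: %d tracks, %d points", n, nrow(object@tracks)))
  if (n > 0) {
    len <- table(object@tracks$track_id)
    cat(sprintf(", length %d-%d frames", min(len), max(len)))
  }
  cat("\n")
})

setMethod("show", "SRUSImage", function(object) {
  cat(sprintf("SRUSImage: %d x %d px at %.3g mm, %.1f%% track-filled\n",
              nrow(object@raster), ncol(object@raster), object@pixelSize,
              100 * mean(object@raster)))
})

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume3D: %d x %d x %d voxels at %.3g um\n",
              d[1L], d[2L], d[3L], object@voxelSizeUm))
})

setMethod("show", "RadiusMap", function(object) {
  fg <- object@radius > 0
  cat(sprintf("RadiusMap: %d vessel voxels", sum(fg)))
  if (any(fg))
    cat(sprintf(", radius %.2f-%.2f voxels", min(object@radius[fg]),
                max(object@radius[fg])))
  cat("\n")
})

setMethod("show", "RegionMasks3D", function(object) {
  cat(sprintf("RegionMasks3D: kidney=%d, cortex=%d, medulla=%d voxels\n",
              sum(object@kidney), sum(object@cortex), sum(object@medulla)))
})

setMethod("show", "AcquisitionParams", function(object) {
  cat(sprintf(
    "AcquisitionParams: %g Hz x %d frames, %g mm px, PSF sigma %g mm\n",
    object@frameRate, object@nFrames, object@pixelSize, object@psfSigma))
  cat(sprintf(
    "  influx %g MB/s, noise %g, motion %g mm / %g s, seed %d\n",
    object@mbInfluxRate, object@noiseSigma, object@motionAmplitude,
    object@motionPeriod, object@seed))
})

setMethod("show", "TrackerParams", function(object) {
  g <- if (is.na(object@maxLinkDistance))
    sprintf("auto (maxSpeed %g mm/s / frame rate)", object@maxSpeed)
  else sprintf("%g mm", object@maxLinkDistance)
  cat(sprintf(
    "TrackerParams: gate %s, min length %d, %d passes (gate scale %g)\n",
    g, object@minTrackLength, object@nHierarchyPasses, object@passGateScale))
})
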