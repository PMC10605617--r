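# Accessor generics. Slot access from user code should go through these.

#' @name ulmvasc-accessors
#' @title Accessors for ulmvasc data classes
#' @description Small accessor generics over the package's S4 containers.
#' @param object an ulmvasc S4 object.
#' @return The slot value (see each method).
NULL

#' @rdname ulmvasc-accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("stackKind", function(object) standardGeneric("stackKind"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("segmentRadii", function(object) standardGeneric("segmentRadii"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("flowSpeeds", function(object) standardGeneric("flowSpeeds"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("boundingBox", function(object) standardGeneric("boundingBox"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("displacement", function(object) standardGeneric("displacement"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("referenceIndex", function(object) standardGeneric("referenceIndex"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("motionConfidence", function(object) standardGeneric("motionConfidence"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("tracks", function(object) standardGeneric("tracks"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("nTracks", function(object) standardGeneric("nTracks"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("trackRaster", function(object) standardGeneric("trackRaster"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("directionMap", function(object) standardGeneric("directionMap"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("volumeData", function(object) standardGeneric("volumeData"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("radiusField", function(object) standardGeneric("radiusField"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("kidneyMask", function(object) standardGeneric("kidneyMask"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("medullaMask", function(object) standardGeneric("medullaMask"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("cortexMask", function(object) standardGeneric("cortexMask"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("trueDetections", function(object) standardGeneric("trueDetections"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("trueTracks", function(object) standardGeneric("trueTracks"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("trueMotion", function(object) standardGeneric("trueMotion"))

#' @rdname ulmvasc-accessors
#' @export
setGeneric("trueTortuosity", function(object) standardGeneric("trueTortuosity"))
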