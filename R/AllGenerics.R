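#' Accessors for ringbump classes
#'
#' Small accessor generics so downstream code never touches slots
#' directly.
#'
#' @param x an object of the documented class.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))
#' @rdname accessors
#' @export
setGeneric("heading", function(x) standardGeneric("heading"))
#' @rdname accessors
#' @export
setGeneric("rotVelocity", function(x) standardGeneric("rotVelocity"))
#' @rdname accessors
#' @export
setGeneric("cueAngle", function(x) standardGeneric("cueAngle"))
#' @rdname accessors
#' @export
setGeneric("sessionKind", function(x) standardGeneric("sessionKind"))
#' @rdname accessors
#' @export
setGeneric("fluorescence", function(x) standardGeneric("fluorescence"))
#' @rdname accessors
#' @export
setGeneric("background", function(x) standardGeneric("background"))
#' @rdname accessors
#' @export
setGeneric("volumeRate", function(x) standardGeneric("volumeRate"))
#' @rdname accessors
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))
#' @rdname accessors
#' @export
setGeneric("pvaAngle", function(x) standardGeneric("pvaAngle"))
#' @rdname accessors
#' @export
setGeneric("pvaMagnitude", function(x) standardGeneric("pvaMagnitude"))
#' @rdname accessors
#' @export
setGeneric("offsets", function(x) standardGeneric("offsets"))
#' @rdname accessors
#' @export
setGeneric("meanAngle", function(x) standardGeneric("meanAngle"))
#' @rdname accessors
#' @export
setGeneric("vectorLength", function(x) standardGeneric("vectorLength"))
#' @rdname accessors
#' @export
setGeneric("inhWeights", function(x) standardGeneric("inhWeights"))
#' @rdname accessors
#' @export
setGeneric("rates", function(x) standardGeneric("rates"))
#' @rdname accessors
#' @export
setGeneric("protocolEvents", function(x) standardGeneric("protocolEvents"))
#' @rdname accessors
#' @export
setGeneric("skeletonNodes", function(x) standardGeneric("skeletonNodes"))
#' @rdname accessors
#' @export
setGeneric("skeletonEdges", function(x) standardGeneric("skeletonEdges"))
#' @rdname accessors
#' @export
setGeneric("attachments", function(x) standardGeneric("attachments"))
#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname accessors
#' @export
setGeneric("ringBasis", function(x) standardGeneric("ringBasis"))

#' @rdname accessors
#' @export
setMethod("timestamps", "BehaviorTrace", function(x) x@t)
#' @rdname accessors
#' @export
setMethod("heading", "BehaviorTrace", function(x) x@heading)
#' @rdname accessors
#' @export
setMethod("rotVelocity", "BehaviorTrace", function(x) x@rotVelocity)
#' @rdname accessors
#' @export
setMethod("cueAngle", "BehaviorTrace", function(x) x@cueAngle)
#' @rdname accessors
#' @export
setMethod("sessionKind", "BehaviorTrace", function(x) x@sessionKind)

#' @rdname accessors
#' @export
setMethod("fluorescence", "RoiSession", function(x) x@fluorescence)
#' @rdname accessors
#' @export
setMethod("background", "RoiSession", function(x) x@background)
#' @rdname accessors
#' @export
setMethod("volumeRate", "RoiSession", function(x) x@volumeRate)
#' @rdname accessors
#' @export
setMethod("stage", "RoiSession", function(x) x@stage)

#' @rdname accessors
#' @export
setMethod("pvaAngle", "PopulationVectorSeries", function(x) x@angle)
#' @rdname accessors
#' @export
setMethod("pvaMagnitude", "PopulationVectorSeries", function(x) x@magnitude)

#' @rdname accessors
#' @export
setMethod("offsets", "OffsetSummary", function(x) x@offsets)
#' @rdname accessors
#' @export
setMethod("meanAngle", "OffsetSummary", function(x) x@meanAngle)
#' @rdname accessors
#' @export
setMethod("vectorLength", "OffsetSummary", function(x) x@vectorLength)

#' @rdname accessors
#' @export
setMethod("inhWeights", "RingNetwork", function(x) x@W)
#' @rdname accessors
#' @export
setMethod("rates", "RingNetwork", function(x) x@r)

#' @rdname accessors
#' @export
setMethod("protocolEvents", "PairingProtocol", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("skeletonNodes", "SkeletonGraph", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("skeletonEdges", "SkeletonGraph", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("attachments", "SkeletonGraph", function(x) x@attachments)

#' @rdname accessors
#' @export
setMethod("meshVertices", "NeuropilMesh", function(x) x@vertices)
#' @rdname accessors
#' @export
setMethod("ringBasis", "NeuropilMesh", function(x) x@basis)

setMethod("show", "BehaviorTrace", function(object) {
  n <- length(object@t)
  dt <- if (n >= 2) diff(object@t[1:2]) else NA_real_
  cat(sprintf("BehaviorTrace: %s, %d timepoints @ %.3g Hz, %.1f s\n",
              object@sessionKind, n,
              if (is.na(dt)) NA else 1 / dt,
              if (n) diff(range(object@t)) else 0))
})

setMethod("show", "RoiSession", function(object) {
  cat(sprintf("RoiSession (%s): 16 x %d volumes @ %.3g Hz\n",
              object@stage, ncol(object@fluorescence), object@volumeRate))
})

setMethod("show", "PairingProtocol", function(object) {
  cat(sprintf(
    "PairingProtocol: %d events (%d locations x %d repeats), offset %.3f rad%s\n",
    nrow(object@events), object@nLocations, object@nRepeats,
    object@enforcedOffset,
    if (all(is.na(object@events$cue_angle))) " (no cue)" else ""))
})

setMethod("show", "PopulationVectorSeries", function(object) {
  cat(sprintf("PopulationVectorSeries: %d timepoints, mean |PVA| = %.3f\n",
              length(object@pva), mean(object@magnitude)))
})

setMethod("show", "OffsetSummary", function(object) {
  cat(sprintf(
    "OffsetSummary: %d timepoints, mean angle %.3f rad, vector length %.3f\n",
    length(object@offsets), object@meanAngle, object@vectorLength))
})

setMethod("show", "RemappingResult", function(object) {
  cat(sprintf(
    "RemappingResult: error %.3f rad (post-0 angle %.3f, post-pi angle %.3f)\n",
    object@error, object@post0@meanAngle, object@postPi@meanAngle))
})

setMethod("show", "RingNetwork", function(object) {
  cat(sprintf(
    "RingNetwork: %d EPG x %d ER, %s gating, weights in [%.3g, %.3g]\n",
    object@params@nEpg, object@params@nEr, object@rule,
    min(object@W), max(object@W)))
})

setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf("SkeletonGraph: %d nodes, %d edges, %d attachments\n",
              nrow(object@nodes), nrow(object@edges),
              nrow(object@attachments)))
})

setMethod("show", "NeuropilMesh", function(object) {
  cat(sprintf("NeuropilMesh: %d vertices%s\n", nrow(object@vertices),
              if (length(object@basis)) ", ring basis fitted" else ""))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: seed %d, %.0f s @ %.3g Hz, OU(tau=%.2g, sigma=%.2g), SNR %.3g\n",
    object@seed, object@duration, 1 / object@dt, object@ouTau,
    object@ouSigma,
    if (object@noiseSd > 0) object@bumpAmplitude / object@noiseSd else Inf))
})
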