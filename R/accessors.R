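# Accessors and show() methods.

#' Accessors for pipeline objects
#'
#' `trackData` and `segmentData` return the underlying data.frames;
#' `frameInterval` the frame interval in seconds; `nTracks` / `nSegments`
#' the number of particles / segments; `trackLengths` the per-particle
#' track length in frames; `stateD`, `stateSigma2`, `stateWeights` the
#' per-state parameters of a fitted model; `stateLabels` and
#' `statePosterior` the hard labels and posterior matrix of a fit;
#' `velocityVectors` the vector table of a STICS field; `grTable` the
#' binned pair-correlation estimate.
#'
#' @param x a pipeline object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trackData", function(x) standardGeneric("trackData"))
#' @rdname accessors
#' @export
setMethod("trackData", "TrackSet", function(x) x@tracks)

#' @rdname accessors
#' @export
setGeneric("segmentData", function(x) standardGeneric("segmentData"))
#' @rdname accessors
#' @export
setMethod("segmentData", "SegmentSet", function(x) x@segments)

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setMethod("frameInterval", "TrackSet", function(x) x@frameInterval)
#' @rdname accessors
#' @export
setMethod("frameInterval", "SegmentSet", function(x) x@frameInterval)

#' @rdname accessors
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))
#' @rdname accessors
#' @export
setMethod("nTracks", "TrackSet", function(x)
  length(unique(paste(x@tracks$particle_id, x@tracks$burst))))

#' @rdname accessors
#' @export
setGeneric("trackLengths", function(x) standardGeneric("trackLengths"))
#' @rdname accessors
#' @export
setMethod("trackLengths", "TrackSet", function(x) {
  tr <- x@tracks
  tab <- table(tr$particle_id)
  stats::setNames(as.integer(tab), names(tab))
})

#' @rdname accessors
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))
#' @rdname accessors
#' @export
setMethod("nSegments", "SegmentSet", function(x)
  length(unique(x@segments$segment_id)))

#' @rdname accessors
#' @export
setGeneric("stateD", function(x) standardGeneric("stateD"))
#' @rdname accessors
#' @export
setMethod("stateD", "StateModel", function(x) x@D)
#' @rdname accessors
#' @export
setMethod("stateD", "PemFit", function(x) x@model@D)

#' @rdname accessors
#' @export
setGeneric("stateSigma2", function(x) standardGeneric("stateSigma2"))
#' @rdname accessors
#' @export
setMethod("stateSigma2", "StateModel", function(x) x@sigma2)
#' @rdname accessors
#' @export
setMethod("stateSigma2", "PemFit", function(x) x@model@sigma2)

#' @rdname accessors
#' @export
setGeneric("stateWeights", function(x) standardGeneric("stateWeights"))
#' @rdname accessors
#' @export
setMethod("stateWeights", "StateModel", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("stateWeights", "PemFit", function(x) x@model@weights)

#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setMethod("stateLabels", "PemFit", function(x)
  stats::setNames(x@labels, x@segmentIds))

#' @rdname accessors
#' @export
setGeneric("statePosterior", function(x) standardGeneric("statePosterior"))
#' @rdname accessors
#' @export
setMethod("statePosterior", "PemFit", function(x) x@posterior)

#' @rdname accessors
#' @export
setGeneric("bestModel", function(x) standardGeneric("bestModel"))
#' @rdname accessors
#' @export
setMethod("bestModel", "PemScan", function(x) x@fits[[as.character(x@bestK)]])

#' @rdname accessors
#' @export
setGeneric("velocityVectors", function(x) standardGeneric("velocityVectors"))
#' @rdname accessors
#' @export
setMethod("velocityVectors", "VelocityField", function(x) x@vectors)

#' @rdname accessors
#' @export
setGeneric("grTable", function(x) standardGeneric("grTable"))
#' @rdname accessors
#' @export
setMethod("grTable", "GrCurve", function(x)
  data.frame(r = x@r, g = x@g, n_pairs = x@nPairs, valid = x@valid))

#' @rdname accessors
#' @export
setGeneric("logLik2", function(x) standardGeneric("logLik2"))
#' @rdname accessors
#' @export
setMethod("logLik2", "StateModel", function(x) x@logLik)
#' @rdname accessors
#' @export
setMethod("logLik2", "PemFit", function(x) x@model@logLik)

#' @rdname accessors
#' @export
setGeneric("bicValue", function(x) standardGeneric("bicValue"))
#' @rdname accessors
#' @export
setMethod("bicValue", "StateModel", function(x) x@bic)
#' @rdname accessors
#' @export
setMethod("bicValue", "PemFit", function(x) x@model@bic)

setMethod("show", "TrackSet", function(object) {
  tr <- object@tracks
  cat(sprintf("TrackSet: %d localizations, %d particles, %d burst(s), dt = %.4g s\n",
              nrow(tr), nTracks(object), length(unique(tr$burst)),
              object@frameInterval))
})

setMethod("show", "SegmentSet", function(object) {
  cat(sprintf("SegmentSet: %d segments of %d frames (dt = %.4g s)\n",
              nSegments(object), object@segLength, object@frameInterval))
})

setMethod("show", "StateModel", function(object) {
  cat(sprintf("StateModel with K = %d state(s); logLik = %.4f, BIC = %.4f%s\n",
              object@K, object@logLik, object@bic,
              if (object@converged) "" else " (not converged)"))
  print(data.frame(state = seq_len(object@K), D = object@D,
                   sigma = sqrt(object@sigma2), weight = object@weights))
})

setMethod("show", "PemFit", function(object) {
  show(object@model)
  cat(sprintf("%d segments classified (maximum-posterior labels)\n",
              length(object@labels)))
})

setMethod("show", "PemScan", function(object) {
  cat("pEM scan over K =", paste(names(object@fits), collapse = ", "), "\n")
  cat("BIC:", paste(sprintf("%.1f", object@bic), collapse = ", "), "\n")
  cat("Selected K* =", object@bestK, "\n")
})

setMethod("show", "MsdCurve", function(object) {
  cat(sprintf("MsdCurve (%s): %d lags\n", object@group, length(object@lag)))
})

setMethod("show", "GrCurve", function(object) {
  cat(sprintf("GrCurve (%s): %d bins, r in [%.3g, %.3g] um\n", object@group,
              length(object@r), min(object@r), max(object@r)))
})

setMethod("show", "VelocityField", function(object) {
  v <- object@vectors
  cat(sprintf("VelocityField: %d vectors (%d valid), %d time window(s)\n",
              nrow(v), sum(v$valid), length(unique(v$window))))
})

setMethod("show", "CoherenceResult", function(object) {
  cat(sprintf(
    "CoherenceResult: n = %d, inward (c > %.2g) = %.3f, outward (c < -%.2g) = %.3f\n",
    object@n, object@threshold, object@inwardFraction, object@threshold,
    object@outwardFraction))
})
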