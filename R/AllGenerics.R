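#' @rdname Waveform-class
#' @param x,object an object.
#' @param ... further arguments for methods.
#' @export
setGeneric("duration", function(x, ...) standardGeneric("duration"))

#' @rdname Waveform-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname Waveform-class
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname EventTrainSet-class
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' @rdname EventTrainSet-class
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname EventTrainSet-class
#' @export
setGeneric("unitCF", function(x) standardGeneric("unitCF"))

#' @rdname EventTrainSet-class
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname BinnedResponse-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname BinnedResponse-class
#' @export
setGeneric("stream", function(x) standardGeneric("stream"))

#' @rdname Spectrogram-class
#' @export
setGeneric("freqAxis", function(x) standardGeneric("freqAxis"))

#' @rdname Spectrogram-class
#' @export
setGeneric("specValues", function(x) standardGeneric("specValues"))

# ---- methods -------------------------------------------------------------

#' @rdname Waveform-class
#' @export
setMethod("duration", "Waveform", function(x, ...)
  length(x@samples) / x@sampleRate)

#' @rdname Waveform-class
#' @export
setMethod("sampleRate", "Waveform", function(x) x@sampleRate)

#' @rdname Waveform-class
#' @export
setMethod("samples", "Waveform", function(x) x@samples)

#' @export
setMethod("length", "Waveform", function(x) length(x@samples))

setMethod("show", "Waveform", function(object) {
  cat(sprintf("Waveform: %d samples @ %.5g Hz (%.3f s), peak %.3g\n",
              length(object@samples), object@sampleRate,
              duration(object),
              if (length(object@samples)) max(abs(object@samples)) else 0))
})

#' @rdname EventTrainSet-class
#' @export
setMethod("duration", "EventTrainSet", function(x, ...) x@duration)

#' @rdname EventTrainSet-class
#' @export
setMethod("nUnits", "EventTrainSet", function(x) nrow(x@units))

#' @rdname EventTrainSet-class
#' @export
setMethod("nTrials", "EventTrainSet", function(x) x@nTrials)

#' @rdname EventTrainSet-class
#' @export
setMethod("unitCF", "EventTrainSet", function(x) {
  stats::setNames(x@units$cf, x@units$unit)
})

#' @rdname EventTrainSet-class
#' @export
setMethod("eventTable", "EventTrainSet", function(x) x@events)

setMethod("show", "EventTrainSet", function(object) {
  ev <- object@events
  cat(sprintf(
    "EventTrainSet: %d units x %d trials, %.3f s, %d events (%.1f%% failures)\n",
    nUnits(object), nTrials(object), object@duration, nrow(ev),
    if (nrow(ev)) 100 * mean(ev$label == "failure") else 0))
  if (nUnits(object))
    cat(sprintf("  CF range: %.0f-%.0f Hz\n", min(object@units$cf),
                max(object@units$cf)))
})

#' @rdname BinnedResponse-class
#' @export
setMethod("frameRate", "BinnedResponse", function(x) x@frameRate)

#' @rdname BinnedResponse-class
#' @export
setMethod("stream", "BinnedResponse", function(x) x@stream)

#' @rdname Spectrogram-class
#' @export
setMethod("frameRate", "Spectrogram", function(x) x@frameRate)

#' @rdname Spectrogram-class
#' @export
setMethod("freqAxis", "Spectrogram", function(x) x@freqAxis)

#' @rdname Spectrogram-class
#' @export
setMethod("specValues", "Spectrogram", function(x) x@values)

#' @rdname Spectrogram-class
#' @export
setMethod("duration", "Spectrogram", function(x, ...)
  nrow(x@values) / x@frameRate)

setMethod("show", "Spectrogram", function(object) {
  cat(sprintf(
    "Spectrogram: %d frames x %d bands @ %g Hz, %.0f-%.0f Hz, dB range [%.1f, %.1f]\n",
    nrow(object@values), ncol(object@values), object@frameRate,
    min(object@freqAxis), max(object@freqAxis),
    min(object@values), max(object@values)))
})

setMethod("show", "ReconstructionKernel", function(object) {
  d <- dim(object@weights)
  cat(sprintf(
    "ReconstructionKernel: %d lags x %d units x %d bands, lambda = %g\n",
    d[1], d[2], d[3], object@ridgeLambda))
})

setMethod("show", "InhibitionParams", function(object) {
  cat(sprintf(
    "InhibitionParams: deltaTc = %.2g ms, tauI = %.2g ms, S = %g, I0 = %.3g Hz, O = %.3g, pSpontFail = %.3g\n",
    1e3 * object@deltaTc, 1e3 * object@tauI, object@slopeS, object@I0,
    object@O, object@pSpontFail))
})

setMethod("show", "CLD", function(object) {
  cat(sprintf("CLD: %d x %d level bins (%.3g dB wide), %d empty columns\n",
              nrow(object@pcond), ncol(object@pcond),
              diff(object@edges[1:2]), length(object@emptyColumns)))
})
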