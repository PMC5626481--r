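#' @import methods
#' @importFrom stats approx cor fft lm coef confint rbinom rpois runif rnorm
#'   sd var quantile nextn convolve
#' @importFrom utils head tail write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#' @importFrom S4Vectors DataFrame
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Waveform: a mono acoustic pressure signal
#'
#' Container for a single-channel sound waveform together with its sampling
#' rate. The nominal rate used throughout is 97656.25 Hz, matching typical
#' auditory-system acquisition hardware (a non-integer rate, which is why the
#' rate is carried explicitly rather than relying on WAV-header integers).
#'
#' @slot samples numeric vector of pressure-like amplitudes (finite).
#' @slot sampleRate sampling rate in Hz (> 0).
#' @export
setClass("Waveform",
  representation(samples = "numeric", sampleRate = "numeric"),
  prototype(samples = numeric(0), sampleRate = 97656.25)
)

setValidity("Waveform", function(object) {
  msg <- NULL
  if (length(object@sampleRate) != 1 || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive finite number")
  if (length(object@samples) && !all(is.finite(object@samples)))
    msg <- c(msg, "samples must all be finite")
  if (is.null(msg)) TRUE else msg
})

#' Construct a Waveform
#'
#' @param samples numeric vector of amplitudes.
#' @param sampleRate sampling rate in Hz.
#' @return A [Waveform-class] object.
#' @examples
#' w <- Waveform(sin(2 * pi * 440 * seq(0, 0.01, by = 1/48000)), 48000)
#' duration(w)
#' @export
Waveform <- function(samples, sampleRate = 97656.25) {
  new("Waveform", samples = as.numeric(samples),
      sampleRate = as.numeric(sampleRate))
}

#' EventTrainSet: labelled spike/event trains for a recorded population
#'
#' Holds, per unit and trial, sorted event times each labelled
#' \code{"success"} (an EPSP that triggered a postsynaptic action potential;
#' the SBC output stream) or \code{"failure"} (EPSP_fail). The ANF input
#' stream is the union of both. Events are stored in long format for
#' efficient vectorised manipulation.
#'
#' @slot events data.frame with columns \code{unit} (integer), \code{trial}
#'   (integer), \code{time} (seconds), \code{label} ("success"/"failure").
#' @slot units data.frame with columns \code{unit} and \code{cf}
#'   (characteristic frequency, Hz).
#' @slot duration recording duration in seconds; all times lie in
#'   \code{[0, duration]}.
#' @slot nTrials number of trials per unit.
#' @export
setClass("EventTrainSet",
  representation(events = "data.frame", units = "data.frame",
                 duration = "numeric", nTrials = "integer")
)

setValidity("EventTrainSet", function(object) {
  ev <- object@events
  msg <- NULL
  need <- c("unit", "trial", "time", "label")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns", paste(need, collapse = ", ")))
  if (!all(c("unit", "cf") %in% names(object@units)))
    return("units must have columns unit, cf")
  if (nrow(ev)) {
    if (!all(ev$label %in% c("success", "failure")))
      msg <- c(msg, "labels must be 'success' or 'failure'")
    if (any(ev$time < 0) || any(ev$time > object@duration))
      msg <- c(msg, "event times must lie in [0, duration]")
    o <- order(ev$unit, ev$trial, ev$time)
    if (is.unsorted(o) && !identical(o, seq_len(nrow(ev)))) {
      # sortedness within (unit, trial) is checked strictly
      sp <- split(ev$time, interaction(ev$unit, ev$trial, drop = TRUE))
      bad <- vapply(sp, function(t) any(diff(t) <= 0), logical(1))
      if (any(bad)) msg <- c(msg, "times must be strictly increasing within a trial")
    }
  }
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Construct an EventTrainSet
#'
#' @param events data.frame with columns unit, trial, time, label.
#' @param units data.frame with columns unit, cf.
#' @param duration recording duration (s).
#' @param nTrials trials per unit; inferred from \code{events} if missing.
#' @return An [EventTrainSet-class].
#' @export
EventTrainSet <- function(events, units, duration,
                          nTrials = max(events$trial, 0L)) {
  events <- as.data.frame(events)
  if (nrow(events)) {
    events <- events[order(events$unit, events$trial, events$time), ,
                     drop = FALSE]
    rownames(events) <- NULL
  }
  new("EventTrainSet", events = events, units = as.data.frame(units),
      duration = as.numeric(duration), nTrials = as.integer(nTrials))
}

#' BinnedResponse: units x time-bin event counts
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"counts"}
#' is a units x time-bins matrix of event counts at a fixed frame rate
#' (default 2 kHz), with per-unit characteristic frequencies in
#' \code{rowData}. This is the population response matrix R(t, n) used by the
#' linear decoder, and the PSTH container r(t) used by the sparsity and
#' inhibition analyses.
#'
#' @slot frameRate binning rate in Hz.
#' @slot stream which event class was binned: "anf", "sbc" or "epsp_fail".
#' @export
setClass("BinnedResponse",
  contains = "SummarizedExperiment",
  representation(frameRate = "numeric", stream = "character")
)

setValidity("BinnedResponse", function(object) {
  msg <- NULL
  if (length(object@frameRate) != 1 || object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (!object@stream %in% c("anf", "sbc", "epsp_fail"))
    msg <- c(msg, "stream must be one of 'anf', 'sbc', 'epsp_fail'")
  m <- SummarizedExperiment::assay(object)
  if (length(m) && (any(m < 0) || any(m != round(m))))
    msg <- c(msg, "counts must be nonnegative integers")
  if (is.null(msg)) TRUE else msg
})

#' Spectrogram: time x frequency power matrix in dB
#'
#' Short-term Fourier magnitude of a stimulus (or a linear reconstruction of
#' one), on a decibel scale (10 log10 power), at a fixed frame rate with an
#' explicit frequency axis.
#'
#' @slot values time x frequency matrix, dB.
#' @slot frameRate frames per second (Hz).
#' @slot freqAxis centre frequency of each column (Hz), strictly increasing.
#' @slot windowSamples STFT window length in source samples.
#' @slot sourceRate sampling rate of the source waveform (Hz).
#' @slot dbFloor floor applied to the dB values (guards log of silence).
#' @export
setClass("Spectrogram",
  representation(values = "matrix", frameRate = "numeric",
                 freqAxis = "numeric", windowSamples = "numeric",
                 sourceRate = "numeric", dbFloor = "numeric")
)

setValidity("Spectrogram", function(object) {
  msg <- NULL
  if (ncol(object@values) != length(object@freqAxis))
    msg <- c(msg, "freqAxis length must match number of columns")
  if (length(object@freqAxis) > 1 && any(diff(object@freqAxis) <= 0))
    msg <- c(msg, "freqAxis must be strictly increasing")
  if (length(object@values) && !all(is.finite(object@values)))
    msg <- c(msg, "values must be finite (dB floor applied)")
  if (is.null(msg)) TRUE else msg
})

#' ReconstructionKernel: linear decoding weights g_f(tau, n)
#'
#' One weight matrix (lags x units) per reconstructed frequency band,
#' estimated by the ridge-regularized normal equation, together with the
#' standardization constants needed to apply it to new responses.
#'
#' @slot weights array \code{[lags, units, bands]} of decoding weights (on
#'   standardized features).
#' @slot lagAxis response lags in seconds (response time relative to the
#'   stimulus frame being predicted).
#' @slot ridgeLambda the ridge parameter applied to the unit-diagonal
#'   (correlation-scaled) response covariance.
#' @slot featureCenter,featureScale per unit-lag feature standardization.
#' @slot bandCenter per-band mean of the training spectrogram (dB); the
#'   reconstruction intercept.
#' @slot freqAxis frequency axis of the bands (Hz).
#' @slot frameRate frames per second shared by responses and spectrogram.
#' @export
setClass("ReconstructionKernel",
  representation(weights = "array", lagAxis = "numeric",
                 ridgeLambda = "numeric", featureCenter = "numeric",
                 featureScale = "numeric", bandCenter = "numeric",
                 freqAxis = "numeric", frameRate = "numeric")
)

setValidity("ReconstructionKernel", function(object) {
  d <- dim(object@weights)
  msg <- NULL
  if (length(d) != 3) return("weights must be a 3-d array [lags, units, bands]")
  if (d[1] != length(object@lagAxis))
    msg <- c(msg, "lagAxis length must match dim 1 of weights")
  if (d[3] != length(object@bandCenter))
    msg <- c(msg, "bandCenter length must match dim 3 of weights")
  if (!all(is.finite(object@weights)))
    msg <- c(msg, "weights must be finite")
  if (is.null(msg)) TRUE else msg
})

#' InhibitionParams: parameters of the subtractive-inhibition model
#'
#' The model integrates the recent history of ANF activity (conduction delay
#' \code{deltaTc}, exponential time constant \code{tauI}), passes the
#' integrated activity AI(t) through a sigmoid with maximum \code{I0} (Hz),
#' inverse slope \code{slopeS} and half-activation offset \code{O}, and
#' deletes the corresponding number of output spikes per time bin. A
#' rate-independent spontaneous failure probability \code{pSpontFail} is
#' applied first.
#'
#' @slot deltaTc conduction delay (s).
#' @slot tauI integration time constant (s), > 0.
#' @slot slopeS inverse slope of the sigmoid (dimensionless).
#' @slot I0 maximal instantaneous subtracted rate (Hz), >= 0.
#' @slot O half-activation offset, in the units of the integrated activity
#'   AI (Hz when the integration kernel has unit area, the default).
#' @slot pSpontFail spontaneous failure probability in [0, 1].
#' @export
setClass("InhibitionParams",
  representation(deltaTc = "numeric", tauI = "numeric", slopeS = "numeric",
                 I0 = "numeric", O = "numeric", pSpontFail = "numeric"),
  prototype(deltaTc = 0.5e-3, tauI = 3e-3, slopeS = 5, I0 = 0, O = 0,
            pSpontFail = 0)
)

setValidity("InhibitionParams", function(object) {
  msg <- NULL
  if (object@tauI <= 0) msg <- c(msg, "tauI must be > 0")
  if (object@I0 < 0) msg <- c(msg, "I0 must be >= 0")
  if (object@pSpontFail < 0 || object@pSpontFail > 1)
    msg <- c(msg, "pSpontFail must be in [0, 1]")
  if (object@deltaTc < 0) msg <- c(msg, "deltaTc must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct InhibitionParams
#'
#' Defaults follow the fixed across-cell values of the model: conduction
#' delay 0.5 ms, integration time constant 3 ms, inverse slope 5. \code{I0},
#' \code{O} and \code{pSpontFail} are the per-cell parameters, normally set
#' by [fitCellParams()].
#'
#' @param deltaTc conduction delay (s).
#' @param tauI integration time constant (s).
#' @param slopeS inverse sigmoid slope.
#' @param I0 maximal subtracted rate (Hz).
#' @param O half-activation offset (units of AI).
#' @param pSpontFail spontaneous failure probability.
#' @return An [InhibitionParams-class].
#' @export
InhibitionParams <- function(deltaTc = 0.5e-3, tauI = 3e-3, slopeS = 5,
                             I0 = 0, O = 0, pSpontFail = 0) {
  new("InhibitionParams", deltaTc = deltaTc, tauI = tauI, slopeS = slopeS,
      I0 = I0, O = O, pSpontFail = pSpontFail)
}

#' CLD: conditional level density
#'
#' Column-normalized joint histogram of reconstructed versus real spectrogram
#' levels: entry \code{[i, j]} is the empirical probability that the
#' reconstruction falls in level bin i given the real stimulus is in level
#' bin j. Every populated column sums to one; empty columns are all-zero and
#' recorded in \code{emptyColumns}.
#'
#' @slot pcond matrix (recon level bin x real level bin) of conditional
#'   probabilities.
#' @slot edges level bin edges (dB), shared by both axes.
#' @slot counts the raw joint counts, retained for reuse.
#' @slot emptyColumns indices of real-level columns with no observations.
#' @export
setClass("CLD",
  representation(pcond = "matrix", edges = "numeric", counts = "matrix",
                 emptyColumns = "integer")
)

setValidity("CLD", function(object) {
  cs <- colSums(object@pcond)
  pop <- setdiff(seq_along(cs), object@emptyColumns)
  msg <- NULL
  if (length(pop) && any(abs(cs[pop] - 1) > 1e-9))
    msg <- c(msg, "populated columns must sum to 1")
  if (any(object@pcond < 0)) msg <- c(msg, "entries must be >= 0")
  if (is.null(msg)) TRUE else msg
})
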