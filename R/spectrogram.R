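#' Short-term Fourier spectrogram at a fixed frame rate
#'
#' The waveform is divided into overlapping sections of
#' \code{windowSamples} samples, section i starting at sample
#' \code{round(i * sourceRate / frameRate)} (i = 0, 1, ...), so the
#' spectrogram frame rate matches the response binning rate (default 2 kHz)
#' even though neighbouring sections overlap by many samples. Each section
#' is windowed (Hann by default; \code{"rectangular"} uses the raw section),
#' Fourier transformed, and the squared magnitude converted to dB
#' (10 log10), floored at \code{max - dbFloorRange} to keep silence finite.
#' The number of frames is
#' \code{floor((length - windowSamples) * frameRate / sourceRate) + 1}.
#'
#' @param wave a [Waveform-class] (length >= windowSamples).
#' @param frameRate output frames per second (Hz, default 2000).
#' @param windowSamples section length in samples (default 512).
#' @param window "hann" or "rectangular".
#' @param dbFloorRange dynamic range below the maximum at which values are
#'   floored (dB, default 60).
#' @return A [Spectrogram-class] with \code{windowSamples/2 + 1} frequency
#'   columns (DC to Nyquist).
#' @export
computeSpectrogram <- function(wave, frameRate = 2000, windowSamples = 512,
                               window = c("hann", "rectangular"),
                               dbFloorRange = 60) {
  window <- match.arg(window)
  x <- samples(wave)
  sr <- sampleRate(wave)
  if (length(x) < windowSamples)
    stop("waveform shorter than one analysis window")
  nFrames <- floor((length(x) - windowSamples) * frameRate / sr) + 1
  starts <- round((seq_len(nFrames) - 1) * sr / frameRate) + 1
  starts <- pmin(starts, length(x) - windowSamples + 1)
  win <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * (seq_len(windowSamples) - 1) /
                      (windowSamples - 1))
  } else rep(1, windowSamples)
  nFreq <- windowSamples %/% 2 + 1
  # frame matrix: windowSamples x nFrames, FFT over columns with mvfft
  idx <- outer(seq_len(windowSamples) - 1L, starts, `+`)
  frames <- matrix(x[idx], windowSamples, nFrames) * win
  mag2 <- abs(stats::mvfft(frames)[seq_len(nFreq), , drop = FALSE])^2
  db <- 10 * log10(pmax(mag2, .Machine$double.xmin))
  floorDb <- max(db) - dbFloorRange
  db[db < floorDb] <- floorDb
  new("Spectrogram", values = t(db), frameRate = frameRate,
      freqAxis = (seq_len(nFreq) - 1) * sr / windowSamples,
      windowSamples = windowSamples, sourceRate = sr, dbFloor = floorDb)
}

#' Restrict a spectrogram to a frequency band
#'
#' Keeps columns with \code{low <= f <= high} (for the default analysis,
#' 300--4400 Hz, slightly extending the characteristic-frequency range of
#' the modelled population).
#'
#' @param spec a [Spectrogram-class].
#' @param low,high band edges in Hz.
#' @return the band-restricted [Spectrogram-class].
#' @export
restrictBand <- function(spec, low = 300, high = 4400) {
  stopifnot(low < high)
  keep <- which(freqAxis(spec) >= low & freqAxis(spec) <= high)
  if (!length(keep)) stop("no frequency bins in the requested band")
  methods::initialize(spec, values = spec@values[, keep, drop = FALSE],
                      freqAxis = spec@freqAxis[keep])
}

#' Construct a Spectrogram directly from a matrix
#'
#' Mostly for tests and for representing reconstructions.
#'
#' @param values time x frequency matrix (dB).
#' @param frameRate frames per second.
#' @param freqAxis frequency per column (Hz).
#' @param windowSamples,sourceRate provenance fields (defaults 512,
#'   97656.25).
#' @return A [Spectrogram-class].
#' @export
Spectrogram <- function(values, frameRate = 2000,
                        freqAxis = seq_len(ncol(values)),
                        windowSamples = 512, sourceRate = 97656.25) {
  new("Spectrogram", values = as.matrix(values), frameRate = frameRate,
      freqAxis = as.numeric(freqAxis), windowSamples = windowSamples,
      sourceRate = sourceRate, dbFloor = min(values))
}
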