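# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

# default 18.7 s stimulus with 2 s silent lead-in, its band-restricted
# spectrogram, and the driven-frame index
defaultStimulusFixture <- function() {
  if (!exists("stim", envir = .fixtures)) {
    wav <- synthesizeStimulus(defaultSegments(), seed = 1)
    padded <- Waveform(c(numeric(round(2 * sampleRate(wav))), samples(wav)),
                       sampleRate(wav))
    spec <- computeSpectrogram(padded)
    specBand <- restrictBand(spec, 300, 4400)
    assign("stim", list(
      wav = wav, padded = padded, spec = spec, specBand = specBand,
      drivenFrames = seq.int(4001L, nrow(specValues(specBand))),
      spontWindow = c(0, 2),
      drivenWindow = c(2, nrow(specValues(specBand)) / 2000)
    ), envir = .fixtures)
  }
  get("stim", envir = .fixtures)
}

# a flat (constant-dB) spectrogram whose CF envelope is constant, for
# homogeneous-rate simulations
flatSpectrogram <- function(durationS, frameRate = 2000, level = 0) {
  n <- floor(durationS * frameRate)
  Spectrogram(matrix(level, n, 8),
              frameRate = frameRate,
              freqAxis = seq(500, 4000, length.out = 8))
}

# hand-built EventTrainSet from a list of per-trial time/label vectors
# (single unit)
makeUnitEvents <- function(trials, durationS, cf = 2000) {
  rows <- list()
  for (j in seq_along(trials)) {
    tr <- trials[[j]]
    if (length(tr$times))
      rows[[length(rows) + 1L]] <- data.frame(
        unit = 1L, trial = j, time = tr$times,
        label = if (is.null(tr$labels)) rep("success", length(tr$times))
                else tr$labels)
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit = integer(0), trial = integer(0), time = numeric(0),
               label = character(0))
  EventTrainSet(ev, units = data.frame(unit = 1L, cf = cf),
                duration = durationS, nTrials = length(trials))
}

# small segment table for fast pipeline tests
tinySegments <- function() {
  list(
    segmentSpec(0.9, 400, 3000, 0.7, 0.02, 0, "a"),
    segmentSpec(0.9, 800, 4000, 0.9, 0.01, 0, "b"),
    segmentSpec(0.9, 400, 2000, 0.3, 0.04, 0, "c")
  )
}
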