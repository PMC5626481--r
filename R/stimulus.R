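#' Describe one stimulus segment
#'
#' A segment is band-limited Gaussian noise multiplied by a slowly varying
#' random envelope. Varying the carrier band and modulation depth across
#' segments emulates environmental sounds of different spectral breadth and
#' amplitude-modulation character (steady broadband rain-like noise at low
#' depth, through nearly fully modulated granular sand-like textures).
#'
#' @param duration segment duration in seconds (> 0).
#' @param bandLow,bandHigh carrier noise band edges in Hz
#'   (\code{bandLow < bandHigh < Nyquist}).
#' @param modulationDepth envelope modulation depth in [0, 1]; 0 gives an
#'   unmodulated carrier, 1 lets the envelope reach zero.
#' @param modulationTimescale autocorrelation scale of the random envelope in
#'   seconds.
#' @param levelOffset segment level relative to the stimulus mean, in dB.
#' @param name optional label.
#' @return A list of class \code{"SegmentSpec"}.
#' @export
segmentSpec <- function(duration, bandLow, bandHigh, modulationDepth = 0.5,
                        modulationTimescale = 0.02, levelOffset = 0,
                        name = "") {
  stopifnot(duration > 0, modulationDepth >= 0, modulationDepth <= 1,
            bandLow < bandHigh, modulationTimescale > 0)
  structure(list(duration = duration, bandLow = bandLow, bandHigh = bandHigh,
                 modulationDepth = modulationDepth,
                 modulationTimescale = modulationTimescale,
                 levelOffset = levelOffset, name = name),
            class = "SegmentSpec")
}

#' Default seven-segment stimulus table
#'
#' Seven segments with crossfades of 460 ms whose total synthesized length is
#' exactly 18.7 s (durations are chosen so that
#' \code{sum(d) - 6 * 0.46 = 18.7}). Spectral content and modulation depths
#' span steady broadband textures (rain-like), narrow-band tonal segments,
#' and near-fully modulated granular textures (sand-like); all carrier bands
#' lie inside 300--4400 Hz so the decoded band covers the stimulus.
#'
#' @return list of [segmentSpec()] objects.
#' @export
defaultSegments <- function() {
  d <- (18.7 + 6 * 0.46) / 7  # 3.0657 s per segment, inclusive of overlap
  list(
    segmentSpec(d,  350, 4300, 0.15, 0.050,  0,  "rain"),
    segmentSpec(d,  400, 1800, 0.60, 0.030,  2,  "stream"),
    segmentSpec(d, 1000, 3200, 0.80, 0.015, -2,  "rustle"),
    segmentSpec(d,  600, 4200, 0.95, 0.008,  0,  "sand"),
    segmentSpec(d,  900, 2500, 0.50, 0.040,  3,  "wind"),
    segmentSpec(d, 1500, 4300, 0.70, 0.012, -1,  "gravel"),
    segmentSpec(d,  350, 2200, 0.40, 0.025,  1,  "leaves")
  )
}

# smooth FFT length (factors 2/3/5 only) so R's mixed-radix FFT never hits
# a large prime
fftLen <- function(n) stats::nextn(n, c(2, 3, 5))

# band-limited Gaussian noise via FFT masking (computed on a padded smooth
# length, truncated to n)
bandNoise <- function(n, bandLow, bandHigh, sampleRate) {
  m <- fftLen(n)
  x <- rnorm(m)
  X <- fft(x)
  f <- (seq_len(m) - 1) * sampleRate / m
  f <- pmin(f, sampleRate - f)  # fold to [0, Nyquist]
  keep <- f >= bandLow & f <= bandHigh
  X[!keep] <- 0
  (Re(fft(X, inverse = TRUE)) / m)[seq_len(n)]
}

# slowly varying positive envelope: low-passed Gaussian noise, exponentiated
# (log-normal), peak-normalized, then mixed with a DC floor by `depth`
segmentEnvelope <- function(n, timescale, depth, sampleRate) {
  if (depth == 0) return(rep(1, n))
  m <- fftLen(n)
  z <- rnorm(m)
  Z <- fft(z)
  f <- (seq_len(m) - 1) * sampleRate / m
  f <- pmin(f, sampleRate - f)
  fc <- 1 / timescale
  Z[f > fc] <- 0
  z <- (Re(fft(Z, inverse = TRUE)) / m)[seq_len(n)]
  if (sd(z) > 0) z <- z / sd(z)
  env <- exp(z)
  env <- env / max(env)
  (1 - depth) + depth * env
}

#' Synthesize a segmented, amplitude-modulated stimulus
#'
#' Concatenates band-limited modulated-noise segments with cos^2/sin^2
#' crossfades: during a transition the outgoing segment is weighted
#' \code{cos^2} and the incoming \code{sin^2} over the crossfade, so the
#' weights sum to one at every sample. Adjacent segments overlap during
#' transitions, hence the total duration is
#' \code{sum(durations) - (n - 1) * crossfade}. With [defaultSegments()] this
#' is exactly 18.7 s. The output is peak-normalized to \code{headroom}.
#'
#' @param segments list of [segmentSpec()] objects (at least one).
#' @param crossfade transition length in seconds; must be shorter than the
#'   shortest segment.
#' @param sampleRate output sampling rate in Hz.
#' @param seed integer seed; the waveform is a deterministic function of it.
#' @param headroom peak amplitude of the normalized output.
#' @return A [Waveform-class].
#' @examples
#' w <- synthesizeStimulus(defaultSegments(), seed = 1)
#' duration(w)  # 18.7
#' @export
synthesizeStimulus <- function(segments, crossfade = 0.46,
                               sampleRate = 97656.25, seed = 1,
                               headroom = 0.9) {
  if (length(segments) < 1) stop("need at least one segment")
  durs <- vapply(segments, `[[`, numeric(1), "duration")
  if (crossfade < 0 || (length(segments) > 1 && crossfade >= min(durs)))
    stop("crossfade must be nonnegative and shorter than the shortest segment")
  set.seed(seed)
  nFade <- round(crossfade * sampleRate)
  segWaves <- lapply(segments, function(s) {
    n <- round(s$duration * sampleRate)
    w <- bandNoise(n, s$bandLow, s$bandHigh, sampleRate) *
      segmentEnvelope(n, s$modulationTimescale, s$modulationDepth, sampleRate)
    rms <- sqrt(mean(w^2))
    if (rms > 0) w <- w / rms
    w * 10^(s$levelOffset / 20)
  })
  nTotal <- sum(lengths(segWaves)) - (length(segWaves) - 1L) * nFade
  out <- numeric(nTotal)
  pos <- 0L
  u <- if (nFade > 0) (seq_len(nFade) - 0.5) / nFade else numeric(0)
  fadeIn <- sin(pi / 2 * u)^2
  for (i in seq_along(segWaves)) {
    w <- segWaves[[i]]
    if (i > 1L && nFade > 0) w[seq_len(nFade)] <- w[seq_len(nFade)] * fadeIn
    if (i < length(segWaves) && nFade > 0) {
      tl <- seq.int(length(w) - nFade + 1L, length(w))
      w[tl] <- w[tl] * (1 - fadeIn)  # cos^2 fade-out
    }
    idx <- pos + seq_along(w)
    out[idx] <- out[idx] + w
    pos <- pos + length(w) - nFade
  }
  peak <- max(abs(out))
  if (peak > 0) out <- out * (headroom / peak)
  Waveform(out, sampleRate)
}

#' Crossfade weights at given positions within a transition
#'
#' Utility exposing the crossfade law used by [synthesizeStimulus()]:
#' returns the outgoing (cos^2) and incoming (sin^2) amplitude weights at
#' fractional positions \code{u} in [0, 1] through the transition. The two
#' weights sum to one everywhere, and both equal 0.5 at the midpoint.
#'
#' @param u numeric vector of fractional positions in [0, 1].
#' @return data.frame with columns \code{outgoing} and \code{incoming}.
#' @export
crossfadeWeights <- function(u) {
  stopifnot(all(u >= 0 & u <= 1))
  data.frame(outgoing = cos(pi / 2 * u)^2, incoming = sin(pi / 2 * u)^2)
}
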