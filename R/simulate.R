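#' Describe one auditory-nerve unit
#'
#' @param cf characteristic frequency in Hz.
#' @param spontRate spontaneous firing rate in Hz (default 71.3, the
#'   population-mean spontaneous ANF rate the generator emulates).
#' @param drivenGain driven rate gain in Hz per unit stimulus envelope
#'   (default 58.4, yielding mean driven rates near 130 Hz at the default
#'   stimulus level).
#' @param tuningBandwidthOctaves FWHM of the Gaussian-in-log-frequency
#'   receptive field, in octaves.
#' @param refractory absolute dead time after each event, in seconds.
#' @param exponent envelope-to-rate nonlinearity exponent (1 = linear).
#' @return A list of class \code{"UnitParams"}.
#' @export
unitParams <- function(cf, spontRate = 71.3, drivenGain = 58.4,
                       tuningBandwidthOctaves = 1, refractory = 0.7e-3,
                       exponent = 1) {
  stopifnot(cf > 0, spontRate >= 0, refractory >= 0,
            tuningBandwidthOctaves > 0)
  structure(list(cf = cf, spontRate = spontRate, drivenGain = drivenGain,
                 tuningBandwidthOctaves = tuningBandwidthOctaves,
                 refractory = refractory, exponent = exponent),
            class = "UnitParams")
}

#' Default synthetic ANF population
#'
#' Characteristic frequencies log-spaced over 1.18--3.05 kHz (the CF range of
#' the recorded sample the generator emulates), with spontaneous rates drawn
#' around 71.3 Hz (SD 31.8, truncated at 10 Hz).
#'
#' @param nUnits number of units (default 32).
#' @param seed integer seed for the per-unit rate draws.
#' @return list of [unitParams()] objects.
#' @export
defaultUnits <- function(nUnits = 32, seed = 1) {
  set.seed(seed + 1000003L)
  cfs <- exp(seq(log(1180), log(3050), length.out = nUnits))
  spont <- pmax(10, rnorm(nUnits, 71.3, 31.8))
  gain <- pmax(10, rnorm(nUnits, 58.4, 25.5))
  lapply(seq_len(nUnits), function(i)
    unitParams(cf = cfs[i], spontRate = spont[i], drivenGain = gain[i]))
}

# Gaussian-in-log-frequency weighted envelope of a spectrogram at `cf`,
# in linear amplitude units, normalized to mean 1 over `normWindow` bins
cfEnvelope <- function(spec, cf, bwOct, normWindow = NULL) {
  f <- freqAxis(spec)
  if (cf < min(f) || cf > max(f))
    stop(sprintf("unit cf %.0f Hz outside spectrogram band [%.0f, %.0f]",
                 cf, min(f), max(f)))
  sdOct <- bwOct / (2 * sqrt(2 * log(2)))
  w <- exp(-0.5 * (log2(f / cf) / sdOct)^2)
  w <- w / sum(w)
  p <- 10^(specValues(spec) / 10)        # dB -> linear power
  env <- sqrt(as.vector(p %*% w))        # amplitude-like envelope
  idx <- if (is.null(normWindow)) seq_along(env) else normWindow
  m <- mean(env[idx])
  if (m > 0) env <- env / m
  env
}

# one inhomogeneous-Poisson trial by thinning, with absolute dead time
thinningTrial <- function(rate, frameRate, durationS, refractory) {
  rMax <- max(rate)
  if (rMax <= 0) return(numeric(0))
  n <- rpois(1, rMax * durationS)
  if (n == 0) return(numeric(0))
  tCand <- sort(runif(n, 0, durationS))
  idx <- pmin(floor(tCand * frameRate) + 1, length(rate))
  keep <- runif(n) < rate[idx] / rMax
  tKeep <- tCand[keep]
  if (refractory > 0 && length(tKeep) > 1) {
    ok <- logical(length(tKeep)); last <- -Inf
    for (i in seq_along(tKeep)) {
      if (tKeep[i] - last >= refractory) { ok[i] <- TRUE; last <- tKeep[i] }
    }
    tKeep <- tKeep[ok]
  }
  tKeep
}

#' Simulate an ANF population response to a stimulus spectrogram
#'
#' Each unit fires as an inhomogeneous Poisson process (thinning algorithm)
#' with instantaneous rate
#' \deqn{r(t) = spont + gain \cdot env_{cf}(t)^{exponent}}
#' where \code{env_cf} is the Gaussian-in-log-frequency weighted stimulus
#' envelope at the unit's CF, normalized to mean one over \code{normWindow}.
#' An absolute refractory dead time is then enforced. All events are
#' initially labelled \code{"success"}; failure labels are assigned by the
#' inhibition model.
#'
#' @param spec a [Spectrogram-class] of the stimulus (dB scale).
#' @param units list of [unitParams()].
#' @param nTrials number of independent trials per unit (>= 1).
#' @param seed integer seed; the full set is deterministic given it.
#' @param normWindow optional integer vector of spectrogram frames over which
#'   the envelope is normalized to mean one (defaults to all frames); use the
#'   driven window when the stimulus includes silent padding.
#' @return An [EventTrainSet-class] with all events labelled success.
#' @export
simulateANFPopulation <- function(spec, units, nTrials, seed = 1,
                                  normWindow = NULL) {
  stopifnot(nTrials >= 1, frameRate(spec) > 0)
  durationS <- duration(spec)
  fr <- frameRate(spec)
  set.seed(seed)
  evList <- vector("list", length(units) * nTrials)
  k <- 0L
  for (i in seq_along(units)) {
    u <- units[[i]]
    env <- cfEnvelope(spec, u$cf, u$tuningBandwidthOctaves, normWindow)
    rate <- u$spontRate + u$drivenGain * env^u$exponent
    for (j in seq_len(nTrials)) {
      tt <- thinningTrial(rate, fr, durationS, u$refractory)
      k <- k + 1L
      if (length(tt))
        evList[[k]] <- data.frame(unit = i, trial = j, time = tt,
                                  label = "success")
    }
  }
  ev <- do.call(rbind, evList[!vapply(evList, is.null, logical(1))])
  if (is.null(ev))
    ev <- data.frame(unit = integer(0), trial = integer(0),
                     time = numeric(0), label = character(0))
  EventTrainSet(ev,
                units = data.frame(unit = seq_along(units),
                                   cf = vapply(units, `[[`, numeric(1), "cf")),
                duration = durationS, nTrials = nTrials)
}
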