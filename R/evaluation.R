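#' Correlation decomposition of a reconstruction against the real stimulus
#'
#' Three complementary Pearson correlations between matched time x frequency
#' dB matrices: \emph{overall} over all spectrotemporal cells;
#' \emph{temporal}, computed per frequency band over time and averaged
#' across bands; and \emph{spectral}, computed per time bin across frequency
#' and averaged across bins. Bands or bins with zero variance in either
#' matrix are excluded. \code{varianceDB} is the standard deviation of the
#' reconstructed dB values (the raw variance is returned alongside as
#' \code{varianceRaw}).
#'
#' @param real,recon [Spectrogram-class] objects (or plain matrices) with
#'   matching shapes.
#' @return list with elements \code{overall}, \code{temporal},
#'   \code{spectral}, \code{varianceDB}, \code{varianceRaw}.
#' @export
correlationDecomposition <- function(real, recon) {
  A <- if (methods::is(real, "Spectrogram")) specValues(real) else as.matrix(real)
  B <- if (methods::is(recon, "Spectrogram")) specValues(recon) else as.matrix(recon)
  if (!all(dim(A) == dim(B))) stop("spectrogram shapes do not match")
  reconQuality(A, B)
}

#' Conditional level density of reconstructed versus real levels
#'
#' Joint histogram over (real level, reconstructed level) pairs taken across
#' all spectrotemporal cells, with each real-level column normalized to sum
#' one, giving the empirical conditional probability density of the
#' reconstructed level given the real one. The normalization highlights
#' behaviour at rare extreme levels. Empty columns remain all-zero and are
#' flagged.
#'
#' @param real,recon matched [Spectrogram-class] objects or matrices (dB).
#' @param binWidth level bin width in dB (default 1).
#' @param edges optional explicit bin edges (dB); supply the same edges to
#'   two calls whose CLDs will be differenced with [cldDifference()].
#' @return A [CLD-class].
#' @export
conditionalLevelDensity <- function(real, recon, binWidth = 1,
                                    edges = NULL) {
  stopifnot(binWidth > 0)
  A <- if (methods::is(real, "Spectrogram")) specValues(real) else as.matrix(real)
  B <- if (methods::is(recon, "Spectrogram")) specValues(recon) else as.matrix(recon)
  if (!all(dim(A) == dim(B))) stop("spectrogram shapes do not match")
  if (diff(range(A)) == 0)
    warning("real spectrogram is constant; CLD has a single populated column")
  if (is.null(edges)) {
    lo <- floor(min(A, B) / binWidth) * binWidth
    hi <- ceiling(max(A, B) / binWidth) * binWidth
    if (hi <= lo) hi <- lo + binWidth
    edges <- seq(lo, hi, by = binWidth)
  } else {
    lo <- edges[1]; binWidth <- diff(edges[1:2])
  }
  nL <- length(edges) - 1L
  bin <- function(v) pmin(pmax(floor((v - lo) / binWidth) + 1L, 1L), nL)
  i <- bin(c(B)); j <- bin(c(A))
  counts <- matrix(tabulate((j - 1L) * nL + i, nbins = nL * nL), nL, nL)
  cs <- colSums(counts)
  pcond <- counts
  pop <- cs > 0
  pcond[, pop] <- sweep(counts[, pop, drop = FALSE], 2, cs[pop], "/")
  new("CLD", pcond = pcond, edges = edges, counts = counts,
      emptyColumns = which(!pop))
}

#' Difference of two conditional level densities
#'
#' Elementwise \code{a - b}; because each populated column of a CLD sums to
#' one, every column of the difference sums to zero, exposing where one
#' reconstruction places relatively more or less probability mass than the
#' other.
#'
#' @param a,b [CLD-class] objects with identical bin edges.
#' @return signed matrix (recon level x real level).
#' @export
cldDifference <- function(a, b) {
  if (length(a@edges) != length(b@edges) ||
      any(abs(a@edges - b@edges) > 1e-12))
    stop("CLD bin edges do not match")
  a@pcond - b@pcond
}

#' Regression slope of reconstructed on real levels
#'
#' Ordinary least-squares slope (with large-sample 95% confidence interval)
#' of the reconstructed levels against the real ones — the yellow regression
#' line through a CLD. A compressed dynamic range shows up as a slope below
#' one.
#'
#' @param realLevels,reconLevels paired numeric vectors (>= 3 values).
#' @return list with \code{slope}, \code{ci} (length 2), \code{intercept}.
#' @export
cldSlope <- function(realLevels, reconLevels) {
  if (length(realLevels) < 3 || length(realLevels) != length(reconLevels))
    stop("need >= 3 paired values")
  if (sd(realLevels) == 0) stop("zero variance in real levels")
  fit <- lm(reconLevels ~ realLevels)
  ci <- confint(fit, "realLevels", level = 0.95)
  list(slope = unname(coef(fit)["realLevels"]), ci = as.numeric(ci),
       intercept = unname(coef(fit)[1]))
}

#' Width of the temporal autocorrelation at relative heights
#'
#' Per frequency band, the mean-subtracted temporal autocorrelation of the
#' dB time course is normalized to its value at zero lag; the width at a
#' relative height h is the full span between the first crossings of h on
#' either side of zero lag (linear interpolation between lag samples).
#' Widths are averaged across bands. Heights never reached within
#' \code{maxLag} are reported as NaN with a warning.
#'
#' @param recon a [Spectrogram-class] (or matrix, time x frequency).
#' @param relativeHeights heights strictly in (0, 1), default
#'   \code{seq(0.1, 0.9, by = 0.1)}.
#' @param maxLag maximum lag searched, seconds (default 0.1).
#' @param frameRate frame rate when \code{recon} is a plain matrix.
#' @return named numeric vector of widths in seconds, one per height.
#' @export
autocorrWidth <- function(recon, relativeHeights = seq(0.1, 0.9, by = 0.1),
                          maxLag = 0.1, frameRate = 2000) {
  stopifnot(all(relativeHeights > 0), all(relativeHeights < 1))
  if (methods::is(recon, "Spectrogram")) {
    fr <- frameRate(recon); M <- specValues(recon)
  } else { fr <- frameRate; M <- as.matrix(recon) }
  L <- min(floor(maxLag * fr), nrow(M) - 1L)
  widths <- matrix(NA_real_, ncol(M), length(relativeHeights))
  for (f in seq_len(ncol(M))) {
    x <- M[, f] - mean(M[, f])
    if (sd(x) == 0) next
    ac <- bandAutocorr(x, L)
    for (h in seq_along(relativeHeights)) {
      cross <- firstCrossing(ac, relativeHeights[h])
      if (!is.na(cross)) widths[f, h] <- 2 * cross / fr
    }
  }
  out <- colMeans(widths, na.rm = TRUE)
  out[is.nan(out)] <- NaN
  if (anyNA(widths) && any(colSums(!is.na(widths)) == 0))
    warning("some relative heights were never crossed within maxLag")
  stats::setNames(out, relativeHeights)
}

# normalized autocorrelation at lags 0..L via FFT
bandAutocorr <- function(x, L) {
  n <- length(x)
  m <- nextn(2 * n, 2)
  X <- fft(c(x, rep(0, m - n)))
  ac <- Re(fft(X * Conj(X), inverse = TRUE))[seq_len(L + 1)]
  ac / ac[1]
}

# interpolated lag (in samples) of the first downward crossing of height h
firstCrossing <- function(ac, h) {
  below <- which(ac < h)
  if (!length(below)) return(NA_real_)
  k <- below[1]
  if (k == 1) return(0)
  (k - 2) + (ac[k - 1] - h) / (ac[k - 1] - ac[k])
}

#' Temporal modulation spectrum of a reconstruction
#'
#' Per frequency band, the power spectral density of the mean-subtracted dB
#' time course (segment-averaged periodogram with \code{nSegments}
#' non-overlapping segments), averaged across bands, plus the integrated
#' power in a requested modulation band (default 100--150 Hz, the range
#' matching the inhibitory time constant's period).
#'
#' @param recon a [Spectrogram-class] or matrix (time x frequency).
#' @param band modulation band of interest, Hz (length 2).
#' @param nSegments number of periodogram segments (default 8; use 1 for an
#'   exactly Parseval-consistent periodogram).
#' @param frameRate frame rate when \code{recon} is a plain matrix.
#' @return list with \code{rate} (modulation frequencies, Hz), \code{psd}
#'   (band-averaged PSD, power per Hz), and \code{bandPower} (integral over
#'   \code{band}).
#' @export
modulationSpectrum <- function(recon, band = c(100, 150), nSegments = 8,
                               frameRate = 2000) {
  if (methods::is(recon, "Spectrogram")) {
    fr <- frameRate(recon); M <- specValues(recon)
  } else { fr <- frameRate; M <- as.matrix(recon) }
  if (band[2] > fr / 2)
    stop("requested modulation band exceeds the Nyquist rate of the frames")
  segLen <- nrow(M) %/% nSegments
  if (segLen < 4) stop("too few frames for the requested segmentation")
  nF <- segLen %/% 2 + 1
  psd <- matrix(0, nF, ncol(M))
  for (f in seq_len(ncol(M))) {
    acc <- numeric(nF)
    for (s in seq_len(nSegments)) {
      x <- M[(s - 1) * segLen + seq_len(segLen), f]
      x <- x - mean(x)
      P <- abs(fft(x)[seq_len(nF)])^2 / (segLen * fr)
      # one-sided: double all bins except DC (and Nyquist when present)
      dbl <- rep(2, nF); dbl[1] <- 1
      if (segLen %% 2 == 0) dbl[nF] <- 1
      acc <- acc + P * dbl
    }
    psd[, f] <- acc / nSegments
  }
  rate <- (seq_len(nF) - 1) * fr / segLen
  avg <- rowMeans(psd)
  df <- fr / segLen
  inBand <- rate >= band[1] & rate <= band[2]
  list(rate = rate, psd = avg, bandPower = sum(avg[inBand]) * df)
}

#' Spectral correlation across frequency separations
#'
#' Correlation between the level fluctuations of frequency-band pairs
#' compared within the same time bin (zero time lag): for a separation of d
#' band steps, the Pearson correlation over time between bands f and f + d,
#' averaged over all pairs at that separation. It quantifies how predictable
#' the envelope level is across frequencies — bands with identical time
#' courses give 1 at every separation, independent bands give 0. A
#' separation of zero is exactly 1. Constant bands yield undefined pair
#' correlations; such pairs are excluded with a warning.
#'
#' @param recon a [Spectrogram-class] or matrix (time x frequency).
#' @param maxSeparation largest separation in band steps (default all).
#' @return data.frame with columns \code{separation} (band steps),
#'   \code{separationHz} (when a frequency axis is available) and
#'   \code{correlation}.
#' @export
spectralCorrelation <- function(recon, maxSeparation = NULL) {
  if (methods::is(recon, "Spectrogram")) {
    M <- specValues(recon); fx <- freqAxis(recon)
  } else { M <- as.matrix(recon); fx <- seq_len(ncol(M)) }
  nF <- ncol(M)
  if (nF < 2) stop("need at least 2 frequency bands")
  if (is.null(maxSeparation)) maxSeparation <- nF - 1L
  step <- mean(diff(fx))
  sds <- apply(M, 2, sd)
  if (any(sds == 0)) warning("constant bands excluded from pair correlations")
  CC <- suppressWarnings(cor(M))  # band x band correlation at zero time lag
  corAt <- function(d) {
    if (d == 0) return(1)
    pairs <- cbind(seq_len(nF - d), seq_len(nF - d) + d)
    vals <- CC[pairs]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(NA_real_)
    mean(vals)
  }
  seps <- 0:maxSeparation
  data.frame(separation = seps, separationHz = seps * step,
             correlation = vapply(seps, corAt, numeric(1)))
}

#' Cohen's U1 nonoverlap effect size
#'
#' The fraction of all observations (both groups pooled) lying outside the
#' overlap region of the two groups' ranges. 0 for identical ranges, 1 for
#' disjoint groups; symmetric in its arguments.
#'
#' @param groupA,groupB nonempty numeric vectors.
#' @return value in [0, 1].
#' @examples
#' cohensU1(c(1, 2, 3), c(3, 4, 5))  # 4/6
#' @export
cohensU1 <- function(groupA, groupB) {
  if (!length(groupA) || !length(groupB)) stop("both groups must be nonempty")
  lo <- max(min(groupA), min(groupB))
  hi <- min(max(groupA), max(groupB))
  if (hi < lo) return(1)
  all <- c(groupA, groupB)
  mean(all < lo | all > hi)
}
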