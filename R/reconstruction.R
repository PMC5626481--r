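# Lagged design matrix: time bins x (unit, lag) features.
# Column order: unit fastest, lag slowest (feature (l, n) at column
# (l-1)*nUnits + n). lagBins are response offsets in bins relative to the
# stimulus frame being predicted (lag l means the response at t + l);
# out-of-range responses are zero-padded.
laggedDesign <- function(counts, lagBins) {
  nU <- nrow(counts); nB <- ncol(counts)
  X <- matrix(0, nB, nU * length(lagBins))
  for (k in seq_along(lagBins)) {
    l <- lagBins[k]
    tIdx <- seq_len(nB) + l
    ok <- tIdx >= 1 & tIdx <= nB
    cols <- (k - 1L) * nU + seq_len(nU)
    X[ok, cols] <- t(counts[, tIdx[ok], drop = FALSE])
  }
  X
}

#' Estimate linear reconstruction kernels by the ridge normal equation
#'
#' Models the stimulus spectrogram band f at frame t as a linear
#' superposition of lagged population responses,
#' \deqn{\hat S(t, f) = \sum_\tau \sum_n g_f(\tau, n) R(t + \tau, n),}
#' and solves for the kernels via the regularized normal equation
#' \deqn{g_f = (C_{RR} + \lambda I)^{-1} C_{RS_f}}
#' with \eqn{C_{RR} = X^\top X} the lagged response covariance and
#' \eqn{C_{RS_f} = X^\top S_f}. Features (unit x lag) are centred and scaled
#' to unit variance and the covariance normalized by the number of frames
#' before adding \eqn{\lambda} to the (then unit) diagonal, which makes
#' \eqn{\lambda} scale-free; spectrogram bands are centred and their means
#' re-added as the prediction intercept.
#'
#' @param binned a [BinnedResponse-class] (population counts).
#' @param spec a [Spectrogram-class] with the same frame rate and duration.
#' @param lags numeric length-2 lag window in seconds, default
#'   \code{c(0, 0.025)}: the stimulus at t is predicted from responses in
#'   \code{[t, t + 25 ms]}.
#' @param ridgeLambda ridge parameter (default 0.1).
#' @param trainFrames optional integer vector of frames used for training
#'   (default all).
#' @param standardize centre/scale features and centre bands before solving
#'   (default TRUE). With FALSE the raw normal equation is solved (covariance
#'   still normalized by the frame count) and the reconstruction is strictly
#'   linear in the response.
#' @return A [ReconstructionKernel-class].
#' @export
estimateKernels <- function(binned, spec, lags = c(0, 0.025),
                            ridgeLambda = 0.1, trainFrames = NULL,
                            standardize = TRUE) {
  fr <- frameRate(binned)
  if (abs(fr - frameRate(spec)) > 1e-9)
    stop("response and spectrogram frame rates differ")
  counts <- SummarizedExperiment::assay(binned)
  S <- specValues(spec)
  nB <- min(ncol(counts), nrow(S))
  counts <- counts[, seq_len(nB), drop = FALSE]
  S <- S[seq_len(nB), , drop = FALSE]
  lagBins <- seq.int(round(lags[1] * fr), round(lags[2] * fr))
  if (!length(lagBins)) stop("empty lag window")
  X <- laggedDesign(counts, lagBins)
  if (is.null(trainFrames)) trainFrames <- seq_len(nB)
  fit <- ridgeFit(X[trainFrames, , drop = FALSE],
                  S[trainFrames, , drop = FALSE], ridgeLambda, standardize)
  new("ReconstructionKernel",
      weights = array(fit$G, dim = c(length(lagBins), nrow(counts), ncol(S))),
      lagAxis = lagBins / fr, ridgeLambda = ridgeLambda,
      featureCenter = fit$center, featureScale = fit$scale,
      bandCenter = fit$intercept, freqAxis = freqAxis(spec), frameRate = fr)
}

# standardized ridge solve shared by estimateKernels and crossvalReconstruct
ridgeFit <- function(X, S, lambda, standardize = TRUE) {
  n <- nrow(X)
  if (!standardize) {
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
    Xs <- X
    icpt <- rep(0, ncol(S))
    A <- crossprod(Xs) / n
    diag(A) <- diag(A) + lambda
    G <- solve(A, crossprod(Xs, S) / n)
    return(list(G = G, center = ctr, scale = scl, intercept = icpt))
  }
  ctr <- colMeans(X)
  scl <- sqrt(pmax(colMeans(X^2) - ctr^2, 0))
  if (all(scl == 0)) stop("all response features are constant; cannot solve")
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  icpt <- colMeans(S)
  Sc <- sweep(S, 2, icpt)
  A <- crossprod(Xs) / n
  diag(A) <- diag(A) + lambda
  G <- solve(A, crossprod(Xs, Sc) / n)
  list(G = G, center = ctr, scale = scl, intercept = icpt)
}

applyKernel <- function(counts, kernel) {
  fr <- kernel@frameRate
  lagBins <- round(kernel@lagAxis * fr)
  X <- laggedDesign(counts, lagBins)
  Xs <- sweep(sweep(X, 2, kernel@featureCenter), 2, kernel@featureScale, "/")
  d <- dim(kernel@weights)
  G <- matrix(kernel@weights, d[1] * d[2], d[3])
  sweep(Xs %*% G, 2, kernel@bandCenter, "+")
}

#' Reconstruct a stimulus spectrogram from population responses
#'
#' Applies estimated kernels to (possibly new) binned responses. A zero
#' response reconstructs the per-band training mean (the intercept).
#'
#' @param binned a [BinnedResponse-class] with the same unit set and frame
#'   rate as the kernels were trained on.
#' @param kernel a [ReconstructionKernel-class].
#' @return A [Spectrogram-class] reconstruction (dB scale, same axes as the
#'   training spectrogram).
#' @export
reconstructStimulus <- function(binned, kernel) {
  counts <- SummarizedExperiment::assay(binned)
  if (nrow(counts) != dim(kernel@weights)[2])
    stop("unit count does not match the kernel")
  if (abs(frameRate(binned) - kernel@frameRate) > 1e-9)
    stop("frame rate does not match the kernel")
  Shat <- applyKernel(counts, kernel)
  Spectrogram(Shat, frameRate = kernel@frameRate, freqAxis = kernel@freqAxis)
}

#' Cross-validated stimulus reconstruction
#'
#' Splits the recording into \code{nSections} contiguous, equal-length
#' sections. For each section, kernels trained on the remaining sections
#' predict it; the predictions are stitched into a full reconstruction. The
#' report carries, per section, the cross-validated and in-sample
#' reconstruction qualities (overall/temporal/spectral correlation and the
#' SD of the reconstructed dB values) and their average, following the
#' convention of averaging cross-validated and in-sample estimates.
#'
#' @param binned a [BinnedResponse-class].
#' @param spec the real [Spectrogram-class] (same frame rate/duration).
#' @param nSections number of contiguous cross-validation sections
#'   (default 10).
#' @param lags lag window in seconds (see [estimateKernels()]).
#' @param ridgeLambda ridge parameter (default 0.1).
#' @return list with \code{reconstruction} (stitched cross-validated
#'   [Spectrogram-class]), \code{report} (data.frame, one row per section)
#'   and \code{summary} (averages over sections of the averaged
#'   cross-validated/in-sample qualities).
#' @export
crossvalReconstruct <- function(binned, spec, nSections = 10,
                                lags = c(0, 0.025), ridgeLambda = 0.1) {
  if (nSections < 2) stop("need at least 2 sections")
  fr <- frameRate(binned)
  counts <- SummarizedExperiment::assay(binned)
  S <- specValues(spec)
  nB <- min(ncol(counts), nrow(S))
  counts <- counts[, seq_len(nB), drop = FALSE]
  S <- S[seq_len(nB), , drop = FALSE]
  lagBins <- seq.int(round(lags[1] * fr), round(lags[2] * fr))
  secLen <- nB %/% nSections
  if (secLen <= length(lagBins))
    stop("sections shorter than the lag window")
  bounds <- c((seq_len(nSections) - 1) * secLen, nB)
  X <- laggedDesign(counts, lagBins)
  # fixed diagonal feature scaling estimated once on the full recording (so
  # lambda stays comparable across folds); centering is exact per training
  # fold via sufficient statistics accumulated per section
  scl <- sqrt(pmax(colMeans(X^2) - colMeans(X)^2, 0))
  if (all(scl == 0)) stop("all response features are constant; cannot solve")
  scl[scl == 0] <- 1
  X <- sweep(X, 2, scl, "/")
  secIdx <- lapply(seq_len(nSections), function(s)
    (bounds[s] + 1):bounds[s + 1])
  Cs <- lapply(secIdx, function(i) crossprod(X[i, , drop = FALSE]))
  Ds <- lapply(secIdx, function(i) crossprod(X[i, , drop = FALSE],
                                             S[i, , drop = FALSE]))
  xs <- lapply(secIdx, function(i) colSums(X[i, , drop = FALSE]))
  ss <- lapply(secIdx, function(i) colSums(S[i, , drop = FALSE]))
  ns <- lengths(secIdx)
  Ctot <- Reduce(`+`, Cs); Dtot <- Reduce(`+`, Ds)
  xtot <- Reduce(`+`, xs); stot <- Reduce(`+`, ss)
  solveFold <- function(C, D, xsum, ssum, n) {
    mx <- xsum / n; ms <- ssum / n
    A <- (C - n * tcrossprod(mx)) / n
    diag(A) <- diag(A) + ridgeLambda
    B <- (D - n * outer(mx, ms)) / n
    list(G = solve(A, B), mx = mx, ms = ms)
  }
  predictWith <- function(fit, rows) {
    sweep(sweep(X[rows, , drop = FALSE], 2, fit$mx) %*% fit$G, 2, fit$ms,
          "+")
  }
  fitAll <- solveFold(Ctot, Dtot, xtot, stot, nB)
  recon <- matrix(NA_real_, nB, ncol(S))
  rows <- vector("list", nSections)
  for (s in seq_len(nSections)) {
    test <- secIdx[[s]]
    fit <- solveFold(Ctot - Cs[[s]], Dtot - Ds[[s]], xtot - xs[[s]],
                     stot - ss[[s]], nB - ns[s])
    recon[test, ] <- predictWith(fit, test)
    qs <- reconQuality(S[test, , drop = FALSE], recon[test, , drop = FALSE])
    ins <- predictWith(fitAll, test)
    qi <- reconQuality(S[test, , drop = FALSE], ins)
    rows[[s]] <- data.frame(section = s,
      corrOverall = qs$overall, corrTemporal = qs$temporal,
      corrSpectral = qs$spectral, varianceDB = qs$varianceDB,
      corrOverallIn = qi$overall, corrTemporalIn = qi$temporal,
      corrSpectralIn = qi$spectral, varianceDBIn = qi$varianceDB)
  }
  report <- do.call(rbind, rows)
  avg <- function(a, b) (a + b) / 2
  summary <- data.frame(
    corrOverall = mean(avg(report$corrOverall, report$corrOverallIn)),
    corrTemporal = mean(avg(report$corrTemporal, report$corrTemporalIn),
                        na.rm = TRUE),
    corrSpectral = mean(avg(report$corrSpectral, report$corrSpectralIn),
                        na.rm = TRUE),
    varianceDB = mean(avg(report$varianceDB, report$varianceDBIn)))
  list(reconstruction = Spectrogram(recon, frameRate = fr,
                                    freqAxis = freqAxis(spec)),
       report = report, summary = summary)
}

# shared correlation decomposition on plain matrices (time x freq)
reconQuality <- function(real, recon) {
  stopifnot(all(dim(real) == dim(recon)))
  overall <- if (sd(real) > 0 && sd(recon) > 0) cor(c(real), c(recon))
             else NA_real_
  perBand <- vapply(seq_len(ncol(real)), function(f) {
    x <- real[, f]; y <- recon[, f]
    if (sd(x) > 0 && sd(y) > 0) cor(x, y) else NA_real_
  }, numeric(1))
  perBin <- vapply(seq_len(nrow(real)), function(t) {
    x <- real[t, ]; y <- recon[t, ]
    if (sd(x) > 0 && sd(y) > 0) cor(x, y) else NA_real_
  }, numeric(1))
  list(overall = overall,
       temporal = mean(perBand, na.rm = TRUE),
       spectral = mean(perBin, na.rm = TRUE),
       varianceDB = sd(c(recon)),
       varianceRaw = var(c(recon)))
}
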