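streamLabels <- function(stream) {
  switch(stream,
         anf = c("success", "failure"),
         sbc = "success",
         epsp_fail = "failure",
         stop("unknown stream selector: ", stream,
              " (use 'anf', 'sbc' or 'epsp_fail')"))
}

#' Bin events into a units x time count matrix
#'
#' Counts events per unit in half-open bins \code{[b/fr, (b+1)/fr)},
#' summed across trials, for the requested event stream: \code{"sbc"}
#' (successes only), \code{"epsp_fail"} (failures only) or \code{"anf"}
#' (all events). The number of bins is \code{floor(duration * frameRate)}.
#'
#' @param events an [EventTrainSet-class].
#' @param stream one of "anf", "sbc", "epsp_fail".
#' @param frameRate binning rate in Hz (default 2000).
#' @return A [BinnedResponse-class] (units x bins counts, CFs in rowData).
#' @export
binEvents <- function(events, stream = "anf", frameRate = 2000) {
  stopifnot(frameRate > 0)
  labs <- streamLabels(stream)
  ev <- eventTable(events)
  ev <- ev[ev$label %in% labs, , drop = FALSE]
  nBins <- floor(duration(events) * frameRate)
  nU <- nUnits(events)
  counts <- matrix(0L, nU, nBins)
  if (nrow(ev)) {
    b <- floor(ev$time * frameRate) + 1L
    keep <- b >= 1L & b <= nBins
    idx <- (b[keep] - 1L) * nU + ev$unit[keep]   # column-major linear index
    tab <- tabulate(idx, nbins = nU * nBins)
    counts <- matrix(as.integer(tab), nU, nBins)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(cf = unname(unitCF(events))))
  new("BinnedResponse", se, frameRate = frameRate, stream = stream)
}

#' Bin one unit's trials separately
#'
#' Trials x time-bins count matrix for a single unit, used by the
#' reproducibility statistic and by per-trial diagnostics.
#'
#' @param events an [EventTrainSet-class].
#' @param unit unit index.
#' @param stream event stream selector (see [binEvents()]).
#' @param frameRate binning rate (Hz).
#' @return integer matrix, trials x bins.
#' @export
binTrials <- function(events, unit, stream = "anf", frameRate = 2000) {
  stopifnot(frameRate > 0)
  labs <- streamLabels(stream)
  ev <- eventTable(events)
  ev <- ev[ev$unit == unit & ev$label %in% labs, , drop = FALSE]
  nBins <- floor(duration(events) * frameRate)
  nT <- nTrials(events)
  m <- matrix(0L, nT, nBins)
  if (nrow(ev)) {
    b <- floor(ev$time * frameRate) + 1L
    keep <- b >= 1L & b <= nBins
    idx <- (b[keep] - 1L) * nT + ev$trial[keep]
    m <- matrix(as.integer(tabulate(idx, nbins = nT * nBins)), nT, nBins)
  }
  m
}

#' Trial-averaged firing rate per unit
#'
#' \code{rate = total events in window / (window length x nTrials)}.
#'
#' @param events an [EventTrainSet-class].
#' @param stream event stream selector.
#' @param window numeric length-2, \code{c(t0, t1)} in seconds; defaults to
#'   the full recording. Events are counted in \code{[t0, t1)}.
#' @return named numeric vector, Hz per unit.
#' @export
firingRate <- function(events, stream = "anf",
                       window = c(0, duration(events))) {
  stopifnot(length(window) == 2)
  if (diff(window) <= 0) stop("window must have positive length")
  labs <- streamLabels(stream)
  ev <- eventTable(events)
  sel <- ev$label %in% labs & ev$time >= window[1] & ev$time < window[2]
  n <- tabulate(ev$unit[sel], nbins = nUnits(events))
  stats::setNames(n / (diff(window) * nTrials(events)),
                  rownames(events@units))
}

#' Failure fraction per unit
#'
#' Fraction of events labelled failure, pooled across trials, within a time
#' window: \code{nFail / (nFail + nSuccess)}. Units with no events in the
#' window get \code{NaN} with a warning.
#'
#' @param events an [EventTrainSet-class].
#' @param window numeric length-2 window in seconds (events in
#'   \code{[t0, t1)}).
#' @return numeric vector per unit in [0, 1] (or NaN).
#' @export
failureFraction <- function(events, window = c(0, duration(events))) {
  ev <- eventTable(events)
  sel <- ev$time >= window[1] & ev$time < window[2]
  nU <- nUnits(events)
  tot <- tabulate(ev$unit[sel], nbins = nU)
  fail <- tabulate(ev$unit[sel & ev$label == "failure"], nbins = nU)
  if (any(tot == 0))
    warning("no events in window for ", sum(tot == 0),
            " unit(s); returning NaN")
  out <- fail / tot
  out[tot == 0] <- NaN
  out
}

#' Variance-based sparsity of a PSTH
#'
#' \deqn{S = 1 - \langle r(t) \rangle_t^2 / \langle r(t)^2 \rangle_t}
#' where the averages run over time bins. S is 0 for a constant rate and
#' approaches 1 for activity concentrated in few bins; for an N-bin input
#' the maximum is \code{1 - 1/N} (all activity in one bin). Setting
#' \code{normalize = TRUE} divides by \code{1 - 1/N} so the upper bound is
#' exactly 1 regardless of N; the default reports the raw formula.
#'
#' @param psth nonnegative rate-over-time vector (>= 2 bins, not all zero).
#' @param normalize apply the \code{1 - 1/N} normalization (default FALSE).
#' @return sparsity in \code{[0, 1 - 1/N]} (raw) or [0, 1] (normalized).
#' @examples
#' sparsity(c(2, 0, 0, 0))  # 0.75
#' sparsity(c(1, 3))        # 0.2
#' @export
sparsity <- function(psth, normalize = FALSE) {
  if (length(psth) < 2) stop("psth must have at least 2 bins")
  if (any(psth < 0)) stop("psth must be nonnegative")
  if (all(psth == 0)) stop("sparsity undefined for an all-zero psth (0/0)")
  s <- 1 - mean(psth)^2 / mean(psth^2)
  if (normalize) s <- s / (1 - 1 / length(psth))
  s
}

#' Trial-to-trial reproducibility of a binned response
#'
#' For every unordered pair of distinct trials (i, j), the raw lag-0
#' cross-correlation \eqn{\sum_t r_i(t) r_j(t)} is divided by
#' \eqn{S_i S_j / N_{bins}} (spike-count product over bin count). The pair
#' values are averaged over all \eqn{N(N-1)/2} pairs and 1 is subtracted, so
#' a fixed-rate Poisson process gives 0 and values above 1 are attainable
#' (identical sparse trains give \code{Nbins/m - 1} for m shared spikes).
#' Pairs containing an empty trial have an undefined normalization; they are
#' excluded and the pair count reduced, with a warning.
#'
#' @param trialMatrix trials x bins count matrix (e.g. from [binTrials()]).
#' @param lagRange integer; if > 0, the full pair-averaged normalized
#'   correlogram over lags \code{-lagRange..lagRange} is also returned (no
#'   zero-padding bias correction at nonzero lags: only lag 0 enters the
#'   statistic).
#' @return If \code{lagRange == 0}, the scalar reproducibility. Otherwise a
#'   list with elements \code{value} and \code{correlogram} (named vector
#'   over lags, with 1 subtracted at lag 0 only in \code{value}).
#' @export
reproducibility <- function(trialMatrix, lagRange = 0) {
  if (nrow(trialMatrix) < 2) stop("need at least 2 trials")
  S <- rowSums(trialMatrix)
  if (any(S == 0)) {
    warning(sum(S == 0), " empty trial(s) excluded from reproducibility")
    trialMatrix <- trialMatrix[S > 0, , drop = FALSE]
    if (nrow(trialMatrix) < 2) stop("fewer than 2 nonempty trials")
    S <- rowSums(trialMatrix)
  }
  nB <- ncol(trialMatrix)
  nT <- nrow(trialMatrix)
  q <- trialMatrix / S              # rows scaled by spike count
  # sum over pairs of Nbins * sum_t q_i q_j, without forming all pairs
  colTot <- colSums(q)
  pairSum <- (sum(colTot^2) - sum(q^2)) / 2
  value <- nB * pairSum / (nT * (nT - 1) / 2) - 1
  if (lagRange == 0) return(value)
  lags <- -lagRange:lagRange
  cg <- vapply(lags, function(L) {
    if (L >= 0) a <- seq_len(nB - L) else a <- seq.int(1 - L, nB)
    b <- a + L
    qa <- q[, a, drop = FALSE]; qb <- q[, b, drop = FALSE]
    ca <- colSums(qa); cb <- colSums(qb)
    ps <- (sum(ca * cb) - sum(qa * qb)) / 2
    nB * ps / (nT * (nT - 1) / 2)
  }, numeric(1))
  names(cg) <- lags
  list(value = value, correlogram = cg)
}

#' Tidy per-unit response metrics table
#'
#' Convenience wrapper computing rate, failure fraction, sparsity and
#' reproducibility per unit and stream.
#'
#' @param events an [EventTrainSet-class].
#' @param streams character vector of stream selectors.
#' @param window analysis window \code{c(t0, t1)} in seconds.
#' @param frameRate binning rate for sparsity/reproducibility (Hz).
#' @return data.frame, one row per unit x stream.
#' @export
responseMetrics <- function(events, streams = c("anf", "sbc", "epsp_fail"),
                            window = c(0, duration(events)),
                            frameRate = 2000) {
  binsIn <- function(m) {
    b0 <- floor(window[1] * frameRate) + 1
    b1 <- floor(window[2] * frameRate)
    m[, b0:min(b1, ncol(m)), drop = FALSE]
  }
  ff <- failureFraction(events, window)
  out <- lapply(streams, function(s) {
    fr <- firingRate(events, s, window)
    sp <- rep(NA_real_, nUnits(events))
    rp <- rep(NA_real_, nUnits(events))
    for (u in seq_len(nUnits(events))) {
      tm <- binsIn(binTrials(events, u, s, frameRate))
      psth <- colSums(tm) * frameRate / nrow(tm)
      if (any(psth > 0) && length(psth) >= 2) sp[u] <- sparsity(psth)
      if (nrow(tm) >= 2 && sum(rowSums(tm) > 0) >= 2)
        rp[u] <- suppressWarnings(reproducibility(tm))
    }
    data.frame(unit = seq_len(nUnits(events)), stream = s, rate = unname(fr),
               failureFraction = ff, sparsity = sp, reproducibility = rp)
  })
  do.call(rbind, out)
}
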