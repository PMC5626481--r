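---
title: "Methods: inhibitory gain control at spherical bushy cells and its cost for stimulus representation"
author: "sbcdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inhibitory gain control at spherical bushy cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Spherical bushy cells (SBCs) in the anteroventral cochlear nucleus receive
giant axosomatic synapses (endbulbs of Held) from auditory nerve fibers
(ANFs). Each presynaptic event produces an EPSP that either triggers a
postsynaptic action potential (a *success*) or fails to (a *failure*); the
failures are largely attributable to acoustically evoked inhibition. The
package implements, on synthetic data, the full analysis chain used to ask
what this inhibition does to the neural representation of natural sounds:

1. spike-train statistics (firing rate, failure fraction, sparsity,
   trial-to-trial reproducibility) for the ANF input stream
   (successes + failures), the SBC output stream (successes only), and the
   failed-EPSP stream;
2. a phenomenological *subtractive inhibition* model that converts ANF
   trains into SBC-like trains by deleting spikes at a rate driven by
   recent input history;
3. linear reconstruction ("decoding") of the stimulus spectrogram from
   lagged population responses via the ridge-regularized normal equation;
4. diagnostics comparing reconstructions across streams: correlation
   decomposition, conditional level densities (CLDs), autocorrelation
   widths, modulation spectra, spectral correlations, and Cohen's U1.

In vivo, inhibition makes SBC responses sparser and more reproducible while
*reducing* overall reconstruction fidelity and compressing the represented
dynamic range. The package's end-to-end tests assert exactly these
directions on synthetic data.

## Synthetic stimulus and ANF generator

The acoustic stimulus emulates a segmented environmental-sound sequence:
seven segments of band-limited Gaussian noise, each multiplied by a slowly
varying log-normal envelope whose modulation depth and timescale differ per
segment (a nearly unmodulated broadband "rain" through an almost fully
modulated "sand"). Segments are joined by 460 ms crossfades in which the
outgoing segment is weighted $\cos^2$ and the incoming $\sin^2$, so
amplitude is conserved at every sample. The stated segment arithmetic
(7 segments, 460 ms transitions, 18.7 s total) is honored by treating the
total as $\sum d_i - 6 \times 0.46$ s and choosing the default per-segment
duration $d = (18.7 + 6 \cdot 0.46)/7 \approx 3.066$ s; the generator takes
durations explicitly, so any other convention can be produced. The sampling
rate is the acquisition-hardware rate 97 656.25 Hz.

Each of the (default 32) ANF units has a characteristic frequency (CF)
log-spaced in 1.18--3.05 kHz and fires as an inhomogeneous Poisson process
(thinning algorithm, followed by a 0.7 ms absolute dead time) with rate

$$r(t) = r_{\mathrm{spont}} + g \cdot \mathrm{env}_{cf}(t)^{\beta},$$

where $\mathrm{env}_{cf}$ is the stimulus envelope weighted by a Gaussian
receptive field in log-frequency around the CF and normalized to unit mean
over the driven window. Defaults $r_\mathrm{spont} = 71.3$ Hz (SD 31.8
across units), $g = 58.4$ Hz and $\beta = 1$ place mean driven rates near
130 Hz, the regime the analysis expects. A configurable silent lead-in
(default 2 s) precedes the stimulus and provides the spontaneous window for
the inhibition fit. The generator deliberately omits cochlear filterbank
realism: no gammatone cascade, no adaptation, no phase locking. Passing
tests therefore demonstrate correctness of the *analysis*, not biological
completeness of the front end.

## Response metrics

All metrics operate on binned counts at a single time base, 2 kHz (0.5 ms
bins), matching the reconstruction frame rate. Bins are half-open
$[b/f_s, (b+1)/f_s)$.

**Sparsity** of the trial-summed PSTH $r(t)$:
$S = 1 - \langle r \rangle_t^2 / \langle r^2 \rangle_t$, 0 for a constant
rate, at most $1 - 1/N$ for $N$ bins. Because the printed formula does not
include the $1/(1 - 1/N)$ normalization some sparseness measures use, both
variants are provided (`normalize` flag, default off = formula as printed).

**Reproducibility**: for every unordered pair of distinct trials the lag-0
cross-correlation $\sum_t r_i(t) r_j(t)$ is divided by $S_i S_j / N_{bins}$
(spike-count product over bin count), averaged over the $N(N-1)/2$ pairs,
and 1 is subtracted. A fixed-rate Poisson process gives 0; $k$ identical
trains with $m$ spikes in $N$ bins give exactly $N/m - 1$, so values above
1 are attainable. Pairs containing an empty trial make the normalization
0/0 and are excluded, reducing the pair count, with a warning. No
zero-padding bias correction is applied at nonzero lags since only lag 0
enters the statistic.

## Subtractive inhibition model

The unit's trial-averaged ANF PSTH is delayed by $\Delta t_c$ and convolved
with a causal exponential kernel of time constant $\tau_I$, giving the
integrated activity $AI(t)$. The kernel is normalized to unit area
(implemented as the recursion $AI_t = a\,AI_{t-1} + (1-a)x_t$ with
$a = e^{-\Delta t/\tau_I}$), so $AI$ is a smoothed rate in Hz and the
sigmoid offset is interpretable in Hz; the unnormalized convention differs
only by rescaling the offset and slope and is available via a flag. The
inhibition rate is

$$SI(t) = \frac{I_0}{1 + e^{-S\,(AI(t) - O)}},$$

with $\Delta t_c = 0.5$ ms, $\tau_I = 3$ ms and $S = 5$ fixed across cells,
and $I_0$ (maximal subtracted rate) and $O$ (half-activation) fitted per
cell. Per time bin, $SI(t) \cdot N_{trials}/f_s$ success events, pooled
across trials, are relabelled as failures, chosen uniformly at random; if
fewer successes exist the bin is emptied. The fractional deletion count is
resolved by stochastic rounding (floor plus a Bernoulli on the fractional
part), which keeps the expected number of deletions exact; deterministic
rounding is available. A rate-independent spontaneous failure probability
is applied first, as an independent Bernoulli relabelling of each success.
The transformation only changes labels — event times are never moved or
created, so the ANF stream is conserved exactly.

**Fitting.** The spontaneous failure probability is set directly to the
spontaneous target. $I_0$ and $O$ are found by exhaustive grid search
(default $25 \times 25$: $I_0 \in [0, 300]$ Hz, $O$ spanning the observed
$AI$ range) minimizing the distance between the achieved and target driven
failure fraction. Exhaustive search is used because spike-count
discreteness produces plateaus that defeat gradient methods. Two exact
simplifications make the grid cheap: the achieved *fraction* depends only
on how many events are deleted per bin, not which; and for integer per-bin
success counts the expectation of $\min(\mathrm{round_{st}}(x), succ)$ over
the stochastic rounding is exactly $\min(x, succ)$, so the expected
fraction given a spontaneous-failure draw is available in closed form.
Near-tied grid points (driven loss within 0.005 of the minimum) are
disambiguated by the spontaneous-window mismatch, so fitted inhibition does
not leak into silence when an equally good non-leaking solution exists.
The history driving $AI$ is the same unit's PSTH; pooling across
similarly tuned fibers, which the biology may do, is out of scope.

## Spectrogram and linear reconstruction

The spectrogram uses overlapping 512-sample sections starting at
$\mathrm{round}(i \cdot SR_{sound}/SR_{spec})$ for frame $i$, so the frame
rate is exactly 2 kHz despite heavy overlap. Sections are Hann-windowed by
default (a rectangular window is available; the choice is not critical for
the band-averaged statistics). Power is displayed as $10\log_{10}$, floored
60 dB below the maximum so silence stays finite. The decoded band is
restricted to 300--4400 Hz (22 FFT bins), slightly extending the CF range.

With responses $R(t, n)$ and spectrogram $S(t, f)$, the decoder assumes

$$\hat S(t,f) = \sum_\tau \sum_n g_f(\tau, n)\, R(t + \tau, n)$$

with response lags $\tau \in [0, 25]$ ms after the predicted frame
(covering ANF/SBC latencies and the \~10 ms inhibitory timescale), and
solves per band

$$g_f = (C_{RR} + \lambda I)^{-1} C_{RS_f}, \qquad \lambda = 0.1 .$$

Unit-lag features are centred and scaled to unit variance and the
covariance is normalized by the frame count before the ridge is added, so
$\lambda$ is scale-free (applied to a unit diagonal); the per-band mean of
the training spectrogram is re-added as the intercept. Reconstruction and
correlations are computed on dB values, which is how spectrograms are
displayed and compared.

**Cross-validation** uses 10 contiguous equal sections; each is predicted
by kernels trained on the rest, and reported qualities are the average of
the cross-validated and in-sample estimates, a convention that reduces the
noise-induced pessimism of pure cross-validation. For efficiency the fold
solutions are assembled from per-section sufficient statistics
($X^\top X$, $X^\top S$, and sums); the diagonal feature scaling is
estimated once on the full recording — a fixed affine feature map that
keeps $\lambda$ comparable across folds — while centering remains exact per
training fold.

## Evaluation diagnostics

- **Correlation decomposition.** Overall Pearson correlation over all
  spectrotemporal cells; *temporal* = per-band correlation over time,
  averaged over bands; *spectral* = per-time-bin correlation across
  frequency, averaged over bins. Constant bands/bins are excluded. The
  spread of the reconstruction is reported as the standard deviation of
  its dB values (`varianceDB`); the raw variance is returned alongside,
  since "variance in dB" is ambiguous between the two conventions.
- **CLD.** Joint histogram of (real, reconstructed) level pairs in 1 dB
  bins, each real-level column normalized to sum one. Column stochasticity
  is enforced by construction; differences of two CLDs on shared edges have
  columns summing to zero. The regression slope of reconstructed on real
  levels summarizes dynamic-range compression.
- **Autocorrelation width.** Per band, the mean-subtracted temporal
  autocorrelation normalized at zero lag (correlation, not covariance,
  base); the width at a relative height is the full span between the first
  crossings on either side of zero, linearly interpolated between lag
  samples, averaged over bands; maximum lag 100 ms. Heights never reached
  are NaN with a warning.
- **Modulation spectrum.** Segment-averaged periodogram of each band's
  mean-subtracted dB time course, averaged over bands, with integrated
  power in a band of interest (default 100--150 Hz, the period range of the
  inhibitory time constant). With one segment the PSD integral equals the
  time-domain variance (Parseval).
- **Spectral correlation.** The stated procedure — a cross-correlation
  across frequencies, compared within each time bin — is implemented as
  the Pearson correlation over time between band pairs $(f, f+d)$ at zero
  time lag, averaged over pairs at each separation $d$. This definition
  satisfies the limiting cases exactly (identical band time courses give 1
  at every separation; independent bands give 0; separation 0 gives 1) and
  measures how predictable envelope fluctuations are across frequency. An
  alternative reading — correlating the raw dB profile across frequency
  within each single time bin — fails the identical-bands limit (the
  profile is constant, its correlation undefined) and is dominated by the
  static spectral envelope, so it was rejected.
- **Cohen's U1**: the fraction of all observations outside the overlap
  region of the two groups' ranges. Only this effect size is implemented
  from its definition; standard hypothesis tests (t, Wilcoxon, ANOVA,
  multiplicity corrections) are delegated to base R and are not a surface
  of this package.

## Numerical choices and degenerate inputs

- Half-open binning; events exactly on a bin edge belong to the later bin.
- All-zero PSTHs make sparsity 0/0: an explicit error. Empty trials break
  the reproducibility normalization: excluded with a warning.
- FFT lengths for noise synthesis are padded to 2/3/5-smooth lengths
  (R's mixed-radix FFT is quadratic at large prime lengths) and truncated.
- The dB floor (max − 60 dB) bounds the CLD support and keeps silence
  finite.
- Stochastic rounding of deletion counts keeps expected deletions unbiased;
  the deterministic alternative biases them by up to half an event per bin.
- All randomness flows from a single global seed through named per-stage
  substreams; pipeline reruns are bit-reproducible.

## Study conditions and what the tests show

The default generator conditions are the study conditions: 32 units with
CFs in 1.18--3.05 kHz, at least 20 trials, an 18.7 s stimulus, spontaneous
rate ~71 Hz, driven ANF rates ~130 Hz, failure-fraction targets 0.36
(spontaneous) and 0.65 (driven), $\lambda = 0.1$, 10 cross-validation
sections. The end-to-end directional checks run a scaled-down study —
16 units, 10 trials, the default stimulus, 5 generator seeds — sizes chosen
so the full suite completes comfortably on a single CPU while leaving the
qualitative comparisons overwhelming clear: relative to the ANF stream,
the simulated SBC stream yields lower overall reconstruction correlation,
a smaller reconstructed-level spread, a flatter CLD slope, narrower
autocorrelation widths at heights ≥ 0.5, and higher spectral correlation
at large (> 2 kHz) separations.

Because the generator is a deliberately minimal Poisson model, the
*magnitudes* of in vivo results (correlations near 0.66/0.71/0.56,
reconstructed SDs near 21/22/16 dB) are not reproduction targets; only the
analytic values, closed forms, and directions of effects are asserted.

## Known limitations

- Same-unit inhibition history; no cross-CF pooling.
- No biophysical synapse model (no EPSP amplitudes, depression, or
  facilitation), no conductances.
- No phase reconstruction or audio resynthesis from reconstructed
  spectrograms; the decoder works on envelope information only.
- The per-segment spectral content of the seven environmental sounds is
  unknown; the synthetic segment table is a stand-in with the right
  diversity, not a calibrated fit.
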