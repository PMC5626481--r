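Package: sbcdecode
Title: Inhibitory Transformation of Auditory Nerve Input at Spherical Bushy
    Cells: Spike-Train Metrics, Subtractive Inhibition, and Linear Stimulus
    Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how acoustically evoked inhibition at the
    endbulb of Held transforms auditory-nerve-fiber (ANF) input into
    spherical-bushy-cell (SBC) output. Provides a synthetic generator for
    segmented, amplitude-modulated acoustic stimuli and inhomogeneous-Poisson
    ANF spike trains; variance-based sparsity and pairwise trial
    reproducibility statistics; an activity-dependent subtractive-inhibition
    model (exponential history integration, sigmoidal activation, stochastic
    spike deletion) with per-cell parameter fitting; ridge-regularized linear
    reconstruction of stimulus spectrograms from lagged population responses
    with cross-validation; and evaluation diagnostics (correlation
    decomposition, conditional level densities, autocorrelation widths,
    modulation spectra, spectral correlation, Cohen's U1).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
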