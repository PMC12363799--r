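Package: alffr
Title: Amplitude of Low-Frequency Fluctuations (ALFF) for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the amplitude of low-frequency fluctuations (ALFF) and
    fractional ALFF (fALFF) of resting-state BOLD fMRI time series in two
    mathematically distinct variants: the arithmetic mean (amALFF/amfALFF) and
    the quadratic mean (qmALFF/qmfALFF) of the one-sided amplitude spectrum.
    The quadratic-mean variants can be computed either in the frequency domain
    from the FFT amplitude spectrum or, via Parseval's theorem, entirely in the
    time domain from the root mean square of a zero-phase Butterworth bandpass
    filtered signal. Includes mean-BOLD-intensity (MBI) diagnostics,
    subject-level map normalization, z-scoring behavior checks, a synthetic
    BOLD generator with known spectral content for validation, group-level
    correlation analysis, and a command-line interface over NIfTI volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
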