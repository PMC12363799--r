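#' Analysis frequency band
#'
#' The band of interest `[fl, fh]` (0.01-0.08 Hz by convention in the ALFF
#' literature) and the preprocessing low-pass cutoff `fc` that bounds the
#' fALFF denominator range (0.2 Hz by convention).
#'
#' @param fl,fh Low and high edge of the band of interest, Hz.
#' @param fc Low-pass cutoff of the preprocessing stage, Hz; the fALFF
#'   denominator runs from just above DC to `fc`.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(fl = 0.01, fh = 0.08, fc = 0.2) {
  if (!(0 < fl && fl < fh && fh < fc))
    stop("band must satisfy 0 < fl < fh < fc; got fl=", fl, " fh=", fh, " fc=", fc)
  structure(list(fl = fl, fh = fh, fc = fc), class = "band_spec")
}

#' Map band edges to FFT bin indices
#'
#' Each frequency maps to the integer bin minimizing `|k * delta_f - f|`
#' where `delta_f = 1/(n * tr)`; ties are broken toward the larger bin and
#' the result is clamped to at least 1 so the DC bin never enters a band.
#'
#' @param band A [band_spec()].
#' @param n Number of timepoints.
#' @param tr Repetition time, seconds.
#' @return An object of class `freq_index` with fields `k_fl`, `k_fh`,
#'   `k_fc`, `n`, `delta_f`.
#' @export
band_indices <- function(band, n, tr) {
  stopifnot(inherits(band, "band_spec"), n >= 8, tr > 0)
  nyquist <- 1 / (2 * tr)
  if (band$fc > nyquist + 1e-12)
    stop("fc = ", band$fc, " Hz exceeds the Nyquist frequency ", nyquist,
         " Hz for tr = ", tr, " s")
  delta_f <- 1 / (n * tr)
  n2 <- n %/% 2
  snap <- function(f) {
    k <- floor(f / delta_f + 0.5)   # round half up: ties toward larger k
    max(1L, min(as.integer(k), n2))
  }
  idx <- list(k_fl = snap(band$fl), k_fh = snap(band$fh), k_fc = snap(band$fc),
              n = as.integer(n), delta_f = delta_f)
  if (!(1L <= idx$k_fl && idx$k_fl <= idx$k_fh && idx$k_fh <= idx$k_fc))
    stop("degenerate bin mapping (k_fl=", idx$k_fl, ", k_fh=", idx$k_fh,
         ", k_fc=", idx$k_fc, "): band too narrow for n=", n, ", tr=", tr)
  structure(idx, class = "freq_index")
}

#' Remove each voxel's temporal mean
#'
#' The per-voxel means of the raw signal are retained in `voxel_means`; the
#' mean BOLD intensity diagnostics are defined on raw, pre-demeaning
#' intensities. Idempotent: demeaning a demeaned series returns it unchanged.
#'
#' @param series A [bold_series()].
#' @return The demeaned [bold_series()].
#' @export
demean <- function(series) {
  stopifnot(inherits(series, "bold_series"))
  if (series$demeaned) return(series)
  out <- series
  out$data <- series$data - rowMeans(series$data)
  out$demeaned <- TRUE
  out
}

#' One-sided FFT amplitude spectrum of every voxel
#'
#' Raw (unscaled) magnitudes `|FFT(s)|` at bins `0 .. floor(n/2)`. For even
#' n the last bin is the Nyquist bin; a real signal's spectrum is symmetric
#' about it, so the one-sided half carries the full information. The series
#' must be demeaned so that bin 0 is analytically zero.
#'
#' @param series A demeaned [bold_series()].
#' @return An object of class `spectrum_set`: `amplitudes` (M x (floor(n/2)+1)),
#'   `freq_grid` (Hz per bin), `n` (original timepoint count), `tr`.
#' @export
amplitude_spectrum <- function(series) {
  stopifnot(inherits(series, "bold_series"))
  if (!series$demeaned) stop("series must be demeaned before spectral analysis")
  n <- ncol(series$data)
  n2 <- n %/% 2
  ft <- stats::mvfft(t(series$data))            # n x M complex
  amp <- t(Mod(ft[seq_len(n2 + 1L), , drop = FALSE]))
  structure(
    list(amplitudes = amp,
         freq_grid = (0:n2) / (n * series$tr),
         n = n, tr = series$tr,
         voxel_index = series$voxel_index, spatial_ref = series$spatial_ref),
    class = "spectrum_set")
}

# Per-bin scaling turning a raw one-sided magnitude into the amplitude of the
# underlying oscillation: 2/n for interior bins (each has a mirrored twin),
# 1/n for the unmirrored Nyquist bin of an even-length series.
onesided_weights <- function(n, k) {
  w <- rep(2 / n, length(k))
  if (n %% 2L == 0L) w[k == n %/% 2L] <- 1 / n
  w
}

check_spec_idx <- function(spec, idx) {
  stopifnot(inherits(spec, "spectrum_set"), inherits(idx, "freq_index"))
  if (spec$n != idx$n)
    stop("frequency index computed for n=", idx$n, " but spectrum has n=", spec$n)
  if (idx$k_fl > idx$k_fh) stop("empty band: k_fl > k_fh")
  invisible(TRUE)
}

spec_map <- function(spec, values, metric_name) {
  voxel_map(values, metric_name,
            voxel_index = spec$voxel_index, spatial_ref = spec$spatial_ref)
}

#' Arithmetic-mean ALFF
#'
#' Per voxel, the arithmetic mean over the in-band bins of the scaled
#' one-sided amplitude `2 S(m,k) / n`: the average oscillation amplitude in
#' the band. This is the classical ALFF definition.
#'
#' @param spec A `spectrum_set` from [amplitude_spectrum()].
#' @param idx A `freq_index` from [band_indices()] computed for the same n.
#' @return A [voxel_map()] named `"amALFF"`.
#' @export
am_alff <- function(spec, idx) {
  check_spec_idx(spec, idx)
  k <- idx$k_fl:idx$k_fh
  w <- onesided_weights(spec$n, k)
  S <- spec$amplitudes[, k + 1L, drop = FALSE]
  spec_map(spec, as.numeric(S %*% w) / length(k), "amALFF")
}

#' Arithmetic-mean fractional ALFF
#'
#' The ratio of summed amplitudes in the band of interest to summed
#' amplitudes over the full analyzed range `(0, fc]`. The DC bin is excluded
#' from the denominator: the series is demeaned, so its contribution is
#' analytically zero and keeping it would only add floating-point dust.
#'
#' @inheritParams am_alff
#' @return A [voxel_map()] named `"amfALFF"` with values in `[0, 1]`.
#' @export
am_falff <- function(spec, idx) {
  check_spec_idx(spec, idx)
  num <- rowSums(spec$amplitudes[, (idx$k_fl:idx$k_fh) + 1L, drop = FALSE])
  den <- rowSums(spec$amplitudes[, (1L:idx$k_fc) + 1L, drop = FALSE])
  v <- num / den
  if (any(den == 0)) {
    warning("flat spectrum in ", sum(den == 0), " voxel(s); fALFF set to NaN")
    v[den == 0] <- NaN
  }
  spec_map(spec, v, "amfALFF")
}

#' Quadratic-mean ALFF (frequency domain)
#'
#' Per voxel, the quadratic (root-mean-square) mean over the in-band bins of
#' the scaled one-sided amplitude `2 S(m,k) / n`. Derived from the mean
#' in-band signal power, it is the amplitude of the equivalent single
#' sinusoid carrying that power, and by Parseval's theorem it can also be
#' computed in the time domain ([qm_alff_time()]).
#'
#' @inheritParams am_alff
#' @return A [voxel_map()] named `"qmALFF"`.
#' @export
qm_alff_freq <- function(spec, idx) {
  check_spec_idx(spec, idx)
  k <- idx$k_fl:idx$k_fh
  w <- onesided_weights(spec$n, k)
  S <- spec$amplitudes[, k + 1L, drop = FALSE]
  spec_map(spec, sqrt(as.numeric((S * S) %*% (w * w)) / length(k)), "qmALFF")
}

#' Quadratic-mean fractional ALFF (frequency domain)
#'
#' Square root of the ratio of in-band to full-range (DC excluded, up to fc)
#' summed squared amplitudes: the fraction of the signal's RMS amplitude
#' that lives in the band.
#'
#' @inheritParams am_alff
#' @return A [voxel_map()] named `"qmfALFF"` with values in `[0, 1]`.
#' @export
qm_falff_freq <- function(spec, idx) {
  check_spec_idx(spec, idx)
  S2 <- spec$amplitudes^2
  num <- rowSums(S2[, (idx$k_fl:idx$k_fh) + 1L, drop = FALSE])
  den <- rowSums(S2[, (1L:idx$k_fc) + 1L, drop = FALSE])
  v <- sqrt(num / den)
  if (any(den == 0)) {
    warning("flat spectrum in ", sum(den == 0), " voxel(s); fALFF set to NaN")
    v[den == 0] <- NaN
  }
  spec_map(spec, v, "qmfALFF")
}
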