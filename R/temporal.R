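#' Butterworth filter specification
#'
#' @param kind `"bandpass"` or `"lowpass"`.
#' @param edges Cutoff frequencies in Hz: length 2 for bandpass, 1 for lowpass.
#' @param order Design order of each pass (default 4). With `zero_lag = TRUE`
#'   the filter is applied forward and backward, which cancels the phase
#'   response and squares the magnitude response; users who read
#'   "fourth-order" as the *effective* two-pass response can set `order = 2`.
#' @param zero_lag Apply forward-backward (zero-phase)? Default `TRUE`.
#' @param edge Edge-transient handling for the zero-phase pass:
#'   `"gust"` (default) solves for the forward and backward initial filter
#'   states that make forward-backward and backward-forward filtering agree
#'   (Gustafsson's method); `"pad"` uses odd-reflection padding of
#'   `3 * (2 * order + 1)` samples with steady-state initialization. The
#'   narrow low-frequency bands used for BOLD analysis have impulse
#'   responses much longer than any reasonable padding, so `"pad"` leaks
#'   substantial edge transients into the output; `"gust"` suppresses them
#'   by orders of magnitude and is the default for that reason.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "lowpass"), edges,
                        order = 4L, zero_lag = TRUE,
                        edge = c("gust", "pad")) {
  kind <- match.arg(kind)
  edge <- match.arg(edge)
  edges <- as.numeric(edges)
  if (kind == "bandpass" && (length(edges) != 2L || edges[1] >= edges[2]))
    stop("bandpass needs edges = c(low, high) with low < high")
  if (kind == "lowpass" && length(edges) != 1L)
    stop("lowpass needs a single cutoff edge")
  if (any(edges <= 0)) stop("filter edges must be positive (Hz)")
  if (order < 1L) stop("filter order must be >= 1")
  structure(list(kind = kind, edges = edges, order = as.integer(order),
                 zero_lag = isTRUE(zero_lag), edge = edge),
            class = "filter_spec")
}

# One causal IIR pass with zero initial state.
iir_pass0 <- function(b, a, x) {
  as.numeric(signal::filter(b, a, x))
}

# One causal IIR pass with steady-state initial conditions: the filter states
# are initialized as if the input had been constant at x[1] forever, which
# suppresses the startup transient (same idea as SciPy's lfilter_zi).
iir_pass_ss <- function(b, a, x) {
  gain <- sum(b) / sum(a)                       # DC gain
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1L], length(b) - 1L),
                            init.y = rep(x[1L] * gain, length(a) - 1L)))
}

# Zero-phase filtering of one series by odd-reflection padding at both ends:
# forward pass, backward pass, trim. padlen samples of padding per end.
filtfilt_pad <- function(b, a, x, padlen) {
  n <- length(x)
  if (n <= padlen)
    stop("series too short for zero-phase padding: need n > ", padlen,
         ", got n = ", n)
  ext <- c(2 * x[1L] - x[(padlen + 1L):2L],
           x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  y <- iir_pass_ss(b, a, ext)
  y <- rev(iir_pass_ss(b, a, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

# Observability matrix of the filter in transposed direct form II: column k
# is the zero-input output response to a unit k-th initial state. Because
# states shift toward the output with no feedback while the output is zero,
# column k is column 1 delayed by k-1 samples.
gust_obs_matrix <- function(b, a, n) {
  ord <- length(a) - 1L
  z <- numeric(ord); z[1L] <- 1
  col1 <- numeric(n)
  for (i in seq_len(n)) {
    y <- z[1L]
    col1[i] <- y
    if (ord > 1L) z[1:(ord - 1L)] <- z[2:ord] - a[2:ord] * y
    z[ord] <- -a[ord + 1L] * y
  }
  Obs <- matrix(0, n, ord)
  Obs[, 1L] <- col1
  for (k in seq_len(ord - 1L))
    Obs[(k + 1L):n, k + 1L] <- col1[1:(n - k)]
  Obs
}

# Zero-phase filtering of the rows of X (voxels x time) by Gustafsson's
# method: choose forward and backward initial states so that
# forward-backward equals backward-forward filtering, removing the edge
# transients that reflection padding leaves behind for narrow low-frequency
# bands. The linear-algebra setup depends only on (b, a, n), so it is built
# once and reused for every voxel.
filtfilt_gust <- function(b, a, X) {
  b <- b / a[1L]; a <- a / a[1L]
  n <- ncol(X)
  Obs <- gust_obs_matrix(b, a, n)
  Obsr <- Obs[n:1L, , drop = FALSE]
  # S applies the filter to the time-reversed propagated initial conditions
  S <- apply(Obsr, 2L, function(col) iir_pass0(b, a, col))
  Sr <- S[n:1L, , drop = FALSE]
  M <- cbind(Sr - Obs, Obsr - S)
  W <- cbind(Sr, Obsr)
  qrM <- qr(M)

  # naive zero-state forward-backward and backward-forward passes, per voxel
  Yfb <- t(apply(X, 1L, function(x) rev(iir_pass0(b, a, rev(iir_pass0(b, a, x))))))
  Ybf <- t(apply(X, 1L, function(x) iir_pass0(b, a, rev(iir_pass0(b, a, rev(x))))))
  # optimal initial conditions minimize the forward/backward disagreement
  ic <- qr.coef(qrM, t(Ybf - Yfb))
  ic[is.na(ic)] <- 0
  Yfb + t(W %*% ic)
}

#' Zero-phase Butterworth filtering of a BOLD series
#'
#' Designs a Butterworth filter of the requested order and applies it
#' forward-backward (zero net phase shift) to every voxel's time series.
#' Edge transients are handled by Gustafsson's method by default, or by
#' odd-reflection padding of `3 * (2 * order + 1)` samples per end with
#' steady-state initialization (`edge = "pad"` in the [filter_spec()]).
#'
#' @param series A demeaned [bold_series()].
#' @param spec A [filter_spec()].
#' @return A [bold_series()] of the same shape; `voxel_means` are carried
#'   over unchanged (they describe the raw signal).
#' @export
butterworth_filter <- function(series, spec) {
  stopifnot(inherits(series, "bold_series"), inherits(spec, "filter_spec"))
  if (!series$demeaned) stop("filter expects a demeaned series")
  n <- ncol(series$data)
  padlen <- 3L * (2L * spec$order + 1L)
  if (n <= padlen)
    stop("n = ", n, " is too short for order-", spec$order,
         " zero-phase filtering; need n > ", padlen)
  nyq <- 1 / (2 * series$tr)
  if (any(spec$edges >= nyq))
    stop("filter edges must lie strictly below the Nyquist frequency ", nyq, " Hz")
  w <- spec$edges / nyq
  bw <- if (spec$kind == "bandpass") signal::butter(spec$order, w, type = "pass")
        else                         signal::butter(spec$order, w, type = "low")
  out <- series
  if (!spec$zero_lag) {
    out$data <- t(apply(series$data, 1L, function(x) iir_pass_ss(bw$b, bw$a, x)))
  } else if (spec$edge == "gust") {
    out$data <- filtfilt_gust(bw$b, bw$a, series$data)
  } else {
    out$data <- t(apply(series$data, 1L, function(x)
      filtfilt_pad(bw$b, bw$a, x, padlen)))
  }
  out
}

# Brick-wall spectral filter used as an exact reference path: zero every FFT
# bin outside [k_lo, k_hi] (and its mirror) and invert the transform.
ideal_bandpass <- function(series, k_lo, k_hi) {
  n <- ncol(series$data)
  ft <- stats::mvfft(t(series$data))
  keep <- rep(FALSE, n)
  ks <- k_lo:k_hi
  keep[ks + 1L] <- TRUE
  keep[(n - ks) %% n + 1L] <- TRUE     # mirrored bins
  ft[!keep, ] <- 0
  out <- series
  out$data <- t(Re(stats::mvfft(ft, inverse = TRUE))) / n
  out
}

#' Per-voxel root mean square
#'
#' @param series A [bold_series()].
#' @return A [voxel_map()] named `"RMS"`.
#' @export
rms <- function(series) {
  stopifnot(inherits(series, "bold_series"))
  map_from_series(series, sqrt(rowMeans(series$data^2)), "RMS")
}

#' Quadratic-mean ALFF computed in the time domain
#'
#' Bandpass-filters the demeaned series to the band of interest and scales
#' the per-voxel RMS by `sqrt(2 / n_bins)`, where `n_bins` is the number of
#' FFT bins in the band. By Parseval's theorem this equals [qm_alff_freq()]
#' exactly when the band selection is ideal (brick-wall); with the
#' Butterworth filter it is an approximation whose error comes from the
#' filter's transition bands.
#'
#' @param series A demeaned [bold_series()].
#' @param band A [band_spec()].
#' @param filter `"butterworth"` (default, the practical path) or `"ideal"`
#'   (brick-wall FFT-mask reference path).
#' @param order Butterworth design order per pass.
#' @param edge Edge handling for the Butterworth path (see [filter_spec()]).
#' @return A [voxel_map()] named `"qmALFF"`.
#' @export
qm_alff_time <- function(series, band, filter = c("butterworth", "ideal"),
                         order = 4L, edge = "gust") {
  filter <- match.arg(filter)
  stopifnot(inherits(series, "bold_series"), inherits(band, "band_spec"))
  if (!series$demeaned) stop("qm_alff_time expects a demeaned series")
  idx <- band_indices(band, ncol(series$data), series$tr)
  bp <- if (filter == "ideal") ideal_bandpass(series, idx$k_fl, idx$k_fh)
        else butterworth_filter(series, filter_spec("bandpass",
                                                    c(band$fl, band$fh),
                                                    order, edge = edge))
  nb <- idx$k_fh - idx$k_fl + 1L
  r <- rms(bp)
  map_from_series(series, sqrt(2 / nb) * r$values, "qmALFF")
}

#' Quadratic-mean fractional ALFF computed in the time domain
#'
#' The ratio of the RMS of the bandpassed signal to the RMS of the signal
#' low-passed at `fc`. When the input already went through the preprocessing
#' low-pass (`lowpass_applied = TRUE`) the raw series RMS is used as the
#' denominator; by default the fc low-pass is applied here.
#'
#' @inheritParams qm_alff_time
#' @param lowpass_applied Set `TRUE` if the series was already low-passed at
#'   `fc` upstream.
#' @return A [voxel_map()] named `"qmfALFF"` with values in `[0, 1]`; filter
#'   ripple can push the raw ratio marginally above 1, in which case it is
#'   clipped with a warning.
#' @export
qm_falff_time <- function(series, band, filter = c("butterworth", "ideal"),
                          order = 4L, edge = "gust", lowpass_applied = FALSE) {
  filter <- match.arg(filter)
  stopifnot(inherits(series, "bold_series"), inherits(band, "band_spec"))
  if (!series$demeaned) stop("qm_falff_time expects a demeaned series")
  idx <- band_indices(band, ncol(series$data), series$tr)
  bp <- if (filter == "ideal") ideal_bandpass(series, idx$k_fl, idx$k_fh)
        else butterworth_filter(series, filter_spec("bandpass",
                                                    c(band$fl, band$fh),
                                                    order, edge = edge))
  lp <- if (lowpass_applied) series
        else if (filter == "ideal") ideal_bandpass(series, 1L, idx$k_fc)
        else butterworth_filter(series, filter_spec("lowpass", band$fc,
                                                    order, edge = edge))
  num <- rms(bp)$values
  den <- rms(lp)$values
  v <- num / den
  if (any(den == 0)) {
    warning("zero low-passed RMS in ", sum(den == 0), " voxel(s); fALFF set to NaN")
    v[den == 0] <- NaN
  }
  over <- which(v > 1)
  if (length(over)) {
    warning("filter ripple pushed the RMS ratio above 1 in ", length(over),
            " voxel(s) (max excess ", format(max(v[over] - 1), digits = 3),
            "); clipped to 1")
    v[over] <- 1
  }
  map_from_series(series, v, "qmfALFF")
}
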