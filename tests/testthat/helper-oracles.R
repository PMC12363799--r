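# Independent oracles and fixture builders shared across the suite.

# Naive O(n^2) DFT: one-sided raw magnitudes at bins 0..floor(n/2), computed
# by direct summation of cosine/sine projections — no FFT anywhere.
naive_dft_mag <- function(x) {
  n <- length(x)
  vapply(0:(n %/% 2L), function(k) {
    ang <- -2 * pi * k * (0:(n - 1L)) / n
    sqrt(sum(x * cos(ang))^2 + sum(x * sin(ang))^2)
  }, numeric(1L))
}

# The four band metrics evaluated directly on naive-DFT magnitudes.
oracle_metrics <- function(x, k_fl, k_fh, k_fc) {
  n <- length(x)
  S <- naive_dft_mag(x - mean(x))
  w <- rep(2 / n, n %/% 2L + 1L)
  if (n %% 2L == 0L) w[n %/% 2L + 1L] <- 1 / n     # Nyquist has no mirror
  band <- (k_fl:k_fh) + 1L
  full <- (1L:k_fc) + 1L
  list(am = mean(S[band] * w[band]),
       qm = sqrt(mean((S[band] * w[band])^2)),
       amf = sum(S[band]) / sum(S[full]),
       qmf = sqrt(sum(S[band]^2) / sum(S[full]^2)))
}

# Exhaustive argmin oracle for frequency -> bin mapping (ties toward larger k).
oracle_band_index <- function(f, n, tr) {
  ks <- 1:(n %/% 2L)
  d <- abs(ks / (n * tr) - f)
  max(ks[d == min(d)])
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)

# A reproducible random multi-voxel series: AR(1)-ish smooth noise.
random_series <- function(m, n, tr = 2, seed = 1) {
  set.seed(seed)
  dat <- t(vapply(seq_len(m), function(i) {
    e <- stats::rnorm(n)
    as.numeric(stats::filter(e, 0.5, method = "recursive"))
  }, numeric(n)))
  bold_series(dat + 100, tr = tr)
}

# Band-dominated series: a few random sinusoids from the band's interior
# plus faint noise. Components sit away from the band edges because a
# Butterworth passes the edge frequencies at half power by definition, so
# edge components can never agree with a brick-wall band selection.
band_dominated_series <- function(m, n = 240, tr = 2, band = band_spec(),
                                  seed = 1) {
  set.seed(seed)
  t <- (0:(n - 1L)) * tr
  df <- 1 / (n * tr)
  margin <- 0.15 * (band$fh - band$fl)
  k_lo <- ceiling((band$fl + margin) / df); k_hi <- floor((band$fh - margin) / df)
  dat <- t(vapply(seq_len(m), function(i) {
    ks <- sample(k_lo:k_hi, 3L)
    amp <- stats::runif(3L, 0.5, 2)
    ph <- stats::runif(3L, 0, 2 * pi)
    x <- rowSums(vapply(1:3, function(j)
      amp[j] * cos(2 * pi * ks[j] * df * t + ph[j]), numeric(n)))
    x + stats::rnorm(n, 0, 0.02)
  }, numeric(n)))
  bold_series(dat, tr = tr)
}

# Write a small 4D BOLD + 3D mask NIfTI pair; returns paths and the array.
write_bold_fixture <- function(dim3 = c(4L, 4L, 4L), nvol = 20L, tr = 2.5,
                               mask_voxels = 10L, constant_voxels = 0L,
                               seed = 7, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("boldfx")
    dir.create(dir)
  }
  set.seed(seed)
  arr <- array(stats::rnorm(prod(dim3) * nvol, mean = 500, sd = 10),
               dim = c(dim3, nvol))
  mask <- array(0L, dim = dim3)
  mask[seq_len(mask_voxels)] <- 1L
  if (constant_voxels > 0L) {
    flat <- seq_len(constant_voxels)
    for (v in flat) arr[v + (seq_len(nvol) - 1L) * prod(dim3)] <- 777
  }
  bold_path <- file.path(dir, "bold.nii.gz")
  mask_path <- file.path(dir, "mask.nii.gz")
  img <- RNifti::asNifti(arr, reference = list(
    pixdim = c(-1, 3, 3, 3, tr, 0, 0, 0)))
  RNifti::writeNifti(img, bold_path)
  RNifti::writeNifti(RNifti::asNifti(mask), mask_path)
  list(bold = bold_path, mask = mask_path, arr = arr, mask_arr = mask, tr = tr)
}
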