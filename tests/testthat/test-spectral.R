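test_that("demean centers rows, keeps raw means, and is idempotent", {
  x <- matrix(c(3, 5, 7, 3, 5, 7, 3, 5), nrow = 1L)
  ser <- bold_series(x, tr = 1)
  dm <- demean(ser)
  expect_equal(rowMeans(dm$data), 0)
  expect_equal(dm$voxel_means, mean(x))
  expect_true(dm$demeaned)
  expect_identical(demean(dm), dm)
  # already centered data is unchanged
  c0 <- bold_series(x - mean(x), tr = 1)
  expect_equal(demean(c0)$data, c0$data)
})

test_that("band_indices maps frequencies to bins with round-half-up ties and DC clamping", {
  b <- band_spec(0.01, 0.08, 0.2)
  idx <- band_indices(b, n = 100, tr = 1.0)
  expect_equal(c(idx$k_fl, idx$k_fh, idx$k_fc), c(1L, 8L, 20L))  # exact grid
  expect_equal(idx$delta_f, 0.01)

  # frozen values from the exhaustive argmin oracle at realistic scan sizes
  i230 <- band_indices(b, n = 230, tr = 2.5)
  expect_equal(c(i230$k_fl, i230$k_fh, i230$k_fc), c(6L, 46L, 115L))
  i1200 <- band_indices(b, n = 1200, tr = 0.72)
  expect_equal(c(i1200$k_fl, i1200$k_fh, i1200$k_fc), c(9L, 69L, 173L))
  for (f in c(0.01, 0.08, 0.15)) {
    expect_equal(band_indices(band_spec(f / 2, f, 0.2), 230, 2.5)$k_fh,
                 oracle_band_index(f, 230, 2.5))
    expect_equal(band_indices(band_spec(f / 2, f, 0.2), 1200, 0.72)$k_fh,
                 oracle_band_index(f, 1200, 0.72))
  }

  # tie exactly between bins 5 and 6 goes up
  expect_equal(band_indices(band_spec(0.01, 0.055, 0.2), 100, 1)$k_fh, 6L)
  # sub-resolution fl clamps to bin 1, never DC
  expect_equal(band_indices(band_spec(0.001, 0.08, 0.2), 100, 1)$k_fl, 1L)
  # invalid bands are rejected
  expect_error(band_spec(0.08, 0.01, 0.2), "fl < fh")
  expect_error(band_indices(band_spec(0.01, 0.08, 0.3), 100, 2), "Nyquist")
})

test_that("amplitude_spectrum matches the closed form for bin-aligned cosines and zero input", {
  n <- 100
  t <- 0:(n - 1)
  x <- 2 * cos(2 * pi * 4 / n * t)
  sp <- amplitude_spectrum(demean(bold_series(rbind(x, 0 * x + 1), tr = 1)))
  expect_equal(unname(sp$amplitudes[1, 5]), 2 * n / 2, tolerance = 1e-12)  # A*n/2 at k0
  expect_lt(max(sp$amplitudes[1, -5]), 1e-9)
  expect_lt(max(sp$amplitudes[2, ]), 1e-9)                        # flat row
  expect_equal(sp$freq_grid, (0:50) / 100)
  expect_error(amplitude_spectrum(bold_series(rbind(x), tr = 1)), "demeaned")
})

test_that("amplitude_spectrum equals the naive O(n^2) DFT for even and odd n", {
  for (n in c(64L, 101L, 240L)) {
    ser <- demean(random_series(3L, n, seed = n))
    sp <- amplitude_spectrum(ser)
    for (i in 1:3) {
      ref <- naive_dft_mag(ser$data[i, ])
      expect_lt(max(abs(sp$amplitudes[i, ] - ref)) / max(ref), 1e-9)
    }
    expect_lt(max(sp$amplitudes[, 1]), 1e-8 * max(sp$amplitudes))  # DC ~ 0
  }
})

test_that("the four band metrics agree with the naive-DFT oracle on random voxels", {
  band <- band_spec()
  for (n in c(64L, 128L, 231L)) {
    ser <- demean(random_series(5L, n, tr = 2, seed = 100 + n))
    idx <- band_indices(band, n, 2)
    sp <- amplitude_spectrum(ser)
    am <- am_alff(sp, idx)$values
    qm <- qm_alff_freq(sp, idx)$values
    amf <- am_falff(sp, idx)$values
    qmf <- qm_falff_freq(sp, idx)$values
    for (i in 1:5) {
      o <- oracle_metrics(ser$data[i, ], idx$k_fl, idx$k_fh, idx$k_fc)
      expect_lt(rel_err(am[i], o$am), 1e-9)
      expect_lt(rel_err(qm[i], o$qm), 1e-9)
      expect_lt(rel_err(amf[i], o$amf), 1e-9)
      expect_lt(rel_err(qmf[i], o$qmf), 1e-9)
    }
  }
})

test_that("single and two-component cosines recover the hand-derived closed forms", {
  n <- 100; t <- 0:(n - 1)
  idx <- band_indices(band_spec(0.01, 0.08, 0.2), n, 1)
  one <- demean(bold_series(rbind(2 * cos(2 * pi * 4 / n * t)), tr = 1))
  sp1 <- amplitude_spectrum(one)
  expect_equal(am_alff(sp1, idx)$values, 0.25, tolerance = 1e-9)        # (2)/8
  expect_equal(qm_alff_freq(sp1, idx)$values, 2 / sqrt(8), tolerance = 1e-9)
  expect_equal(am_falff(sp1, idx)$values, 1, tolerance = 1e-12)
  expect_equal(qm_falff_freq(sp1, idx)$values, 1, tolerance = 1e-12)

  two <- demean(bold_series(rbind(2 * cos(2 * pi * 4 / n * t) +
                                  2 * cos(2 * pi * 15 / n * t)), tr = 1))
  sp2 <- amplitude_spectrum(two)
  expect_equal(am_falff(sp2, idx)$values, 0.5, tolerance = 1e-9)
  expect_equal(qm_falff_freq(sp2, idx)$values, 1 / sqrt(2), tolerance = 1e-9)
})

test_that("scaling the series scales ALFF linearly and leaves fALFF fixed", {
  ser <- demean(random_series(4L, 240L, seed = 5))
  idx <- band_indices(band_spec(), 240L, 2)
  base <- amplitude_spectrum(ser)
  for (c in c(0.3, 17)) {
    sc <- ser; sc$data <- c * ser$data
    sps <- amplitude_spectrum(sc)
    expect_lt(max(rel_err(am_alff(sps, idx)$values, c * am_alff(base, idx)$values)), 1e-10)
    expect_lt(max(rel_err(qm_alff_freq(sps, idx)$values, c * qm_alff_freq(base, idx)$values)), 1e-10)
    expect_lt(max(rel_err(am_falff(sps, idx)$values, am_falff(base, idx)$values)), 1e-10)
    expect_lt(max(rel_err(qm_falff_freq(sps, idx)$values, qm_falff_freq(base, idx)$values)), 1e-10)
  }
})

test_that("qmALFF dominates amALFF with equality only for single-bin spectra", {
  ser <- demean(random_series(50L, 128L, seed = 11))
  idx <- band_indices(band_spec(), 128L, 2)
  sp <- amplitude_spectrum(ser)
  am <- am_alff(sp, idx)$values
  qm <- qm_alff_freq(sp, idx)$values
  expect_true(all(qm >= am * (1 - 1e-12)))
  expect_true(all(qm > am))   # broadband spectra: strict inequality
  # equality iff all in-band amplitudes are equal; cleanest case is a
  # band that maps to a single FFT bin
  one_bin <- band_indices(band_spec(0.039, 0.041, 0.2), 128L, 2)
  expect_equal(one_bin$k_fl, one_bin$k_fh)
  expect_equal(am_alff(sp, one_bin)$values, qm_alff_freq(sp, one_bin)$values,
               tolerance = 1e-12)
})

test_that("fALFF metrics stay within [0, 1] and Parseval holds for demeaned series", {
  ser <- demean(random_series(20L, 230L, tr = 2.5, seed = 3))
  idx <- band_indices(band_spec(), 230L, 2.5)
  sp <- amplitude_spectrum(ser)
  expect_true(all(am_falff(sp, idx)$values >= -1e-9 &
                  am_falff(sp, idx)$values <= 1 + 1e-9))
  expect_true(all(qm_falff_freq(sp, idx)$values >= -1e-9 &
                  qm_falff_freq(sp, idx)$values <= 1 + 1e-9))
  # sum over all n bins of S^2 / n equals sum s^2 (two-sided reconstruction)
  n <- 230L
  for (i in c(1L, 10L)) {
    S <- sp$amplitudes[i, ]
    two_sided <- c(S[1], S[2:(n %/% 2L)], S[n %/% 2L + 1L], rev(S[2:(n %/% 2L)]))
    expect_equal(sum(two_sided^2) / n, sum(ser$data[i, ]^2), tolerance = 1e-9)
  }
})
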