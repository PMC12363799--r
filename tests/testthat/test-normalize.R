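test_that("subject-level MBI is the mean of per-voxel temporal means, pre-demeaning", {
  dat <- rbind(rep(100, 10), rep(300, 10))
  ser <- bold_series(dat, tr = 2)
  expect_equal(mbi_subject(ser), 200)
  expect_equal(mbi_subject(demean(ser)), 200)       # survives demeaning
  set.seed(2)
  noisy <- bold_series(dat + rnorm(20), tr = 2)
  expect_identical(mbi_subject(zscore(noisy)), mbi_subject(noisy))
  z <- bold_series(matrix(0, 2, 10), tr = 2)
  expect_equal(mbi_subject(z), 0)
})

test_that("voxel-level MBI averages per-voxel means across subjects", {
  set.seed(4)
  base <- matrix(rnorm(5 * 16, 100, 5), 5, 16)
  s1 <- bold_series(base, tr = 2)
  s2 <- bold_series(3 * base, tr = 2)
  expect_equal(mbi_voxel(list(s1))$values, rowMeans(base))
  expect_equal(mbi_voxel(list(s1, s2))$values, 2 * rowMeans(base))
  expect_equal(mbi_voxel(list(s2, s1))$values, mbi_voxel(list(s1, s2))$values)
  s3 <- bold_series(base[1:3, ], tr = 2)
  expect_error(mbi_voxel(list(s1, s3)), "mask support")
})

test_that("normalize_map yields unit mean, cancels gains, and is idempotent", {
  m <- voxel_map(c(1, 2, 3), "amALFF")
  nm <- normalize_map(m)
  expect_equal(nm$values, c(0.5, 1.0, 1.5))
  expect_equal(nm$metric_name, "amALFF_norm")
  expect_equal(mean(nm$values), 1, tolerance = 1e-12)
  expect_equal(normalize_map(nm)$values, nm$values)            # idempotent
  for (c in c(0.1, 1, 17)) {
    sc <- m; sc$values <- c * m$values
    expect_equal(normalize_map(sc)$values, nm$values, tolerance = 1e-12)
  }
  bad <- voxel_map(c(-1, -2), "x")
  expect_error(normalize_map(bad), "mean")
})

test_that("zscore gives unit-RMS rows, is idempotent, and scales the spectrum by 1/sigma", {
  x <- rep(c(-2, 0, 2), 4)
  ser <- bold_series(rbind(x), tr = 1)
  zs <- zscore(ser)
  expect_equal(zs$data[1, ], x / sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(rms(zs)$values, 1, tolerance = 1e-12)
  expect_equal(zscore(zs)$data, zs$data, tolerance = 1e-12)

  set.seed(9)
  ser2 <- random_series(4L, 128L, seed = 9)
  sg <- voxel_sigma(ser2)
  spz <- amplitude_spectrum(zscore(ser2))
  sp <- amplitude_spectrum(demean(ser2))
  for (i in 1:4)
    expect_lt(max(abs(spz$amplitudes[i, -1] - sp$amplitudes[i, -1] / sg[i])) /
                max(sp$amplitudes[i, ] / sg[i]), 1e-10)
  # sample-sd convention is exposed; its rows have RMS sqrt((n-1)/n), not 1
  expect_equal(rms(zscore(ser2, sample = TRUE))$values,
               rep(sqrt(127 / 128), 4), tolerance = 1e-12)
})

test_that("fALFF is invariant under z-scoring; ALFF is not when sigma varies", {
  ser <- random_series(10L, 240L, seed = 14)
  idx <- band_indices(band_spec(), 240L, 2)
  sp <- amplitude_spectrum(demean(ser))
  spz <- amplitude_spectrum(zscore(ser))
  expect_lt(max(rel_err(am_falff(spz, idx)$values, am_falff(sp, idx)$values)), 1e-10)
  expect_lt(max(rel_err(qm_falff_freq(spz, idx)$values,
                        qm_falff_freq(sp, idx)$values)), 1e-10)
  sg <- voxel_sigma(ser)
  expect_gt(stats::sd(sg), 0)
  expect_gt(max(rel_err(am_alff(spz, idx)$values, am_alff(sp, idx)$values)), 0.01)
  expect_gt(max(rel_err(qm_alff_freq(spz, idx)$values,
                        qm_alff_freq(sp, idx)$values)), 0.01)
})

test_that("znorm_map divides by sigma then renormalizes, matching the full z-scored pipeline", {
  # hand arithmetic
  m <- voxel_map(c(1, 1), "qmALFF")
  zn <- znorm_map(m, c(1, 2))
  expect_equal(zn$values, c(4 / 3, 2 / 3))
  expect_equal(zn$metric_name, "qmALFF_norm_z")
  # all sigma equal -> znorm == norm exactly
  m2 <- voxel_map(c(1, 2, 5), "qmALFF")
  expect_equal(znorm_map(m2, rep(2.5, 3))$values, normalize_map(m2)$values)
  expect_error(znorm_map(m2, c(1, 2)), "length")
  expect_error(znorm_map(m2, c(1, -1, 2)), "positive")

  # two-path equivalence on synthetic data: pipeline on z-scored series equals
  # znorm_map applied to the map from the raw series
  ser <- random_series(12L, 240L, seed = 23)
  idx <- band_indices(band_spec(), 240L, 2)
  sg <- voxel_sigma(ser)
  path_a <- normalize_map(qm_alff_freq(amplitude_spectrum(zscore(ser)), idx))
  path_b <- znorm_map(qm_alff_freq(amplitude_spectrum(demean(ser)), idx), sg)
  expect_lt(max(rel_err(path_a$values, path_b$values)), 1e-9)
})

test_that("shared_variance is the squared Pearson correlation with its edge cases", {
  set.seed(31)
  v <- rnorm(100)
  a <- voxel_map(v, "a")
  expect_equal(shared_variance(a, a), 1)
  neg <- voxel_map(-v, "b")
  expect_equal(shared_variance(a, neg), 1)              # sign-blind
  b <- voxel_map(rnorm(10000), "c")
  a2 <- voxel_map(rnorm(10000), "d")
  expect_lt(shared_variance(a2, b), 0.01)               # independent maps
  expect_error(shared_variance(a, voxel_map(rep(1, 100), "k")), "constant")
  expect_error(shared_variance(voxel_map(1:2, "x"), voxel_map(2:3, "y")), "3 voxels")

  # znorm differs from norm strictly whenever sigma varies
  ser <- random_series(50L, 240L, seed = 37)
  idx <- band_indices(band_spec(), 240L, 2)
  qm <- qm_alff_freq(amplitude_spectrum(demean(ser)), idx)
  sg <- voxel_sigma(ser)
  sv <- shared_variance(normalize_map(qm), znorm_map(qm, sg))
  expect_lt(sv, 1)
})
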