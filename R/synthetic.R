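#' Specification of a synthetic BOLD dataset
#'
#' Each voxel's series is built as
#' `gain[subject] * (mbi_base + sum of sinusoidal components + white noise)`,
#' so subjects differing only in `mbi_gain` are exact multiplicative rescalings
#' of one another — the structure that makes mean BOLD intensity (MBI)
#' collinear with un-normalized ALFF across subjects. Components and noise
#' have known spectral content, so every estimator can be checked against
#' analytic ground truth.
#'
#' @param n_subjects,n_voxels,n_timepoints Dataset dimensions. Defaults: a
#'   single subject with 100 voxels of 240 timepoints.
#' @param tr Repetition time, seconds (default 2: spectral resolution
#'   1/480 Hz, comfortably below a 0.01 Hz band edge).
#' @param components Data frame with columns `freq` (Hz), `amp`, `phase`
#'   (radians) and optionally `voxel` (1-based index; `NA` = all voxels).
#'   Defaults to a single in-band 0.04 Hz component of amplitude 2.
#' @param noise_sd Standard deviation of additive Gaussian white noise
#'   (before gain scaling).
#' @param mbi_base Baseline intensity added to every voxel (scanner units).
#' @param mbi_gain Per-subject multiplicative gain, recycled to `n_subjects`.
#' @param snap_to_grid Round component frequencies to the nearest nonzero
#'   FFT bin so that noiseless fixtures have exactly known spectra.
#' @param independent_noise If `TRUE`, each (subject, voxel) pair gets its
#'   own noise stream; by default the stream is keyed by voxel only, so a
#'   cohort differing only in `mbi_gain` is an exact multiplicative family.
#' @param grid_dim 3D toy grid on which the voxels live (default 6 x 6 x 6;
#'   voxels occupy the first `n_voxels` positions in native array order).
#' @param seed Master seed; one reproducible stream is derived per voxel, so
#'   partial regeneration and gain-only cohorts are bit-stable.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_subjects = 1L, n_voxels = 100L, n_timepoints = 240L,
                       tr = 2, components = NULL, noise_sd = 0,
                       mbi_base = 500, mbi_gain = 1, snap_to_grid = TRUE,
                       independent_noise = FALSE,
                       grid_dim = c(6L, 6L, 6L), seed = 1L) {
  if (is.null(components))
    components <- data.frame(freq = 0.04, amp = 2, phase = 0, voxel = NA_integer_)
  components <- as.data.frame(components)
  if (is.null(components$phase)) components$phase <- 0
  if (is.null(components$voxel)) components$voxel <- NA_integer_
  stopifnot(all(c("freq", "amp") %in% names(components)),
            all(components$freq > 0), all(components$freq < 1 / (2 * tr)),
            all(components$amp >= 0), mbi_base >= 0, noise_sd >= 0,
            n_voxels <= prod(grid_dim), length(seed) == 1L)
  mbi_gain <- rep_len(as.numeric(mbi_gain), n_subjects)
  structure(
    list(n_subjects = as.integer(n_subjects), n_voxels = as.integer(n_voxels),
         n_timepoints = as.integer(n_timepoints), tr = tr,
         components = components, noise_sd = noise_sd,
         mbi_base = mbi_base, mbi_gain = mbi_gain,
         snap_to_grid = isTRUE(snap_to_grid),
         independent_noise = isTRUE(independent_noise),
         grid_dim = as.integer(grid_dim), seed = as.integer(seed)),
    class = "synth_spec")
}

# Stable per-stream seed below 2^31, derived arithmetically from the master
# seed. By default keyed by voxel only, so that subjects differing only in
# gain share the same underlying realization; with independent_noise the
# subject index enters the key too.
voxel_stream_seed <- function(seed, voxel, subject = 0L) {
  (abs(seed) * 1000003 + subject * 10007 + voxel * 7919) %% 2147483647
}

snap_freq <- function(f, n, tr) {
  df <- 1 / (n * tr)
  pmax(1, round(f / df)) * df
}

#' Generate one synthetic voxel time series
#'
#' @param spec A [synth_spec()].
#' @param subject,voxel 1-based indices.
#' @return Numeric vector of length `n_timepoints`.
#' @export
make_voxel <- function(spec, subject = 1L, voxel = 1L) {
  stopifnot(inherits(spec, "synth_spec"),
            subject >= 1L, subject <= spec$n_subjects,
            voxel >= 1L, voxel <= spec$n_voxels)
  n <- spec$n_timepoints
  t <- (0:(n - 1L)) * spec$tr
  comp <- spec$components
  comp <- comp[is.na(comp$voxel) | comp$voxel == voxel, , drop = FALSE]
  x <- rep(spec$mbi_base, n)
  if (nrow(comp)) {
    f <- if (spec$snap_to_grid) snap_freq(comp$freq, n, spec$tr) else comp$freq
    for (i in seq_len(nrow(comp)))
      x <- x + comp$amp[i] * cos(2 * pi * f[i] * t + comp$phase[i])
  }
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(voxel_stream_seed(spec$seed, voxel,
                               if (spec$independent_noise) subject else 0L))
    x <- x + stats::rnorm(n, 0, spec$noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  spec$mbi_gain[subject] * x
}

#' Generate a full synthetic cohort with its ground-truth table
#'
#' Builds one [bold_series()] per subject on a shared toy grid, plus a table
#' of per-voxel ground truth for the deterministic part of the signal: the
#' baseline intensity, the RMS of in-band components, the RMS of all
#' components, and the in-band power fraction `rho` (noise excluded).
#'
#' @param spec A [synth_spec()].
#' @param band A [band_spec()] defining which components count as in-band
#'   for the ground-truth table.
#' @return A list with elements `subjects` (list of [bold_series()]) and
#'   `truth` (data frame, one row per voxel).
#' @export
make_dataset <- function(spec, band = band_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  d <- spec$grid_dim
  flat <- seq_len(spec$n_voxels)
  idx <- arrayInd(flat, d)
  ref <- list(dim = d, affine = diag(c(3, 3, 3, 1)))

  subjects <- lapply(seq_len(spec$n_subjects), function(s) {
    dat <- t(vapply(flat, function(v) make_voxel(spec, s, v),
                    numeric(spec$n_timepoints)))
    bold_series(dat, tr = spec$tr, voxel_index = idx, spatial_ref = ref,
                demeaned = FALSE)
  })

  comp <- spec$components
  f <- if (spec$snap_to_grid) snap_freq(comp$freq, spec$n_timepoints, spec$tr)
       else comp$freq
  truth <- do.call(rbind, lapply(flat, function(v) {
    sel <- is.na(comp$voxel) | comp$voxel == v
    fin <- f[sel]; amp <- comp$amp[sel]
    inband <- fin >= band$fl & fin <= band$fh
    p_in <- sum(amp[inband]^2 / 2)
    p_tot <- sum(amp^2 / 2)
    data.frame(voxel = v, mbi_base = spec$mbi_base,
               rms_inband = sqrt(p_in), rms_total = sqrt(p_tot),
               rho = if (p_tot > 0) p_in / p_tot else NA_real_)
  }))
  list(subjects = subjects, truth = truth)
}

#' Write a synthetic dataset to disk as NIfTI fixtures
#'
#' Materializes each subject as a 4D NIfTI volume, plus the shared 3D mask
#' and the ground-truth table as tab-separated text.
#'
#' @param spec A [synth_spec()].
#' @param out_dir Output directory (created if needed).
#' @param band Passed to [make_dataset()].
#' @return Invisibly, a list of the written file paths.
#' @export
write_dataset <- function(spec, out_dir, band = band_spec()) {
  ds <- make_dataset(spec, band)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- spec$grid_dim
  mask <- array(0L, dim = d)
  mask[seq_len(spec$n_voxels)] <- 1L
  mask_path <- file.path(out_dir, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(mask), mask_path)
  bold_paths <- vapply(seq_along(ds$subjects), function(s) {
    ser <- ds$subjects[[s]]
    arr <- array(0, dim = c(d, spec$n_timepoints))
    flat3 <- seq_len(spec$n_voxels)
    for (tt in seq_len(spec$n_timepoints))
      arr[flat3 + (tt - 1L) * prod(d)] <- ser$data[, tt]
    p <- file.path(out_dir, sprintf("sub-%03d_bold.nii.gz", s))
    img <- RNifti::asNifti(arr, reference = list(
      pixdim = c(-1, 3, 3, 3, spec$tr, 0, 0, 0)))
    RNifti::writeNifti(img, p)
    p
  }, character(1L))
  truth_path <- file.path(out_dir, "ground_truth.tsv")
  utils::write.table(ds$truth, truth_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(list(bold = bold_paths, mask = mask_path, truth = truth_path))
}
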