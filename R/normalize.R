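#' Subject-level mean BOLD intensity
#'
#' The mean over in-mask voxels of each voxel's temporal mean, computed from
#' the raw (pre-demeaning, pre-filtering) intensities. MBI reflects scanner
#' settings and participant physiology and is the quantity whose correlation
#' with un-normalized ALFF motivates subject-level normalization.
#'
#' @param series A [bold_series()] (demeaned or not; the raw per-voxel means
#'   are retained through demeaning).
#' @return A single number in scanner units.
#' @export
mbi_subject <- function(series) {
  stopifnot(inherits(series, "bold_series"))
  mean(series$voxel_means)
}

#' Voxel-level mean BOLD intensity across subjects
#'
#' Per voxel, the mean over subjects of that voxel's temporal mean. All
#' subjects must share the same mask support.
#'
#' @param subjects A list of [bold_series()] on a common mask.
#' @return A [voxel_map()] named `"MBI"`.
#' @export
mbi_voxel <- function(subjects) {
  stopifnot(length(subjects) >= 1L)
  check_same_support(subjects)
  mu <- rowMeans(vapply(subjects, function(s) s$voxel_means,
                        numeric(n_voxels(subjects[[1L]]))))
  map_from_series(subjects[[1L]], mu, "MBI")
}

check_same_support <- function(subjects) {
  ref <- subjects[[1L]]
  for (s in subjects[-1L]) {
    if (n_voxels(s) != n_voxels(ref))
      stop("subjects have differing mask support: ", n_voxels(ref),
           " vs ", n_voxels(s), " voxels")
    if (!is.null(ref$voxel_index) && !is.null(s$voxel_index) &&
        !identical(ref$voxel_index, s$voxel_index))
      stop("subjects have differing voxel coordinates despite equal counts")
  }
  invisible(TRUE)
}

#' Normalize a metric map to unit mask mean
#'
#' Divides every value by the map's mean over the mask so the subject's map
#' averages exactly 1. Any multiplicative factor common to all voxels
#' (gain, intensity scaling, spectral scaling conventions) cancels, which is
#' what removes the MBI dependence of ALFF across subjects. Idempotent.
#'
#' @param map A [voxel_map()] with positive mask mean.
#' @return The normalized [voxel_map()], `metric_name` suffixed `"_norm"`.
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "voxel_map"))
  m <- mean(map$values)
  if (!is.finite(m) || m <= 0)
    stop("cannot normalize: map mean over mask is ", m)
  out <- map
  out$values <- map$values / m
  if (!endsWith(map$metric_name, "_norm"))
    out$metric_name <- paste0(map$metric_name, "_norm")
  out
}

#' Per-voxel temporal standard deviation
#'
#' @param series A [bold_series()].
#' @param sample Use the sample (n-1) convention instead of the population
#'   (n) convention. The population convention is the default so that
#'   z-scored rows have RMS exactly 1.
#' @return Numeric vector of per-voxel standard deviations.
#' @export
voxel_sigma <- function(series, sample = FALSE) {
  stopifnot(inherits(series, "bold_series"))
  x <- series$data - rowMeans(series$data)
  n <- ncol(x)
  sqrt(rowSums(x^2) / (if (sample) n - 1L else n))
}

#' z-score every voxel's time series
#'
#' Demeans each row and divides by its temporal standard deviation
#' (population convention by default, so each row's RMS is exactly 1).
#' z-scoring scales a voxel's whole amplitude spectrum by `1/sigma` and
#' removes the DC term: fractional metrics are unaffected, un-normalized
#' ALFF is not. Idempotent. The raw per-voxel means are retained for MBI.
#'
#' @inheritParams voxel_sigma
#' @return A z-scored, demeaned [bold_series()].
#' @export
zscore <- function(series, sample = FALSE) {
  stopifnot(inherits(series, "bold_series"))
  sg <- voxel_sigma(series, sample = sample)
  if (any(sg == 0))
    stop(sum(sg == 0), " voxel(s) have zero temporal variance; ",
         "they should have been dropped at read")
  out <- series
  out$data <- (series$data - rowMeans(series$data)) / sg
  out$demeaned <- TRUE
  out
}

#' z-scored-and-normalized variant of an ALFF map
#'
#' Divides each voxel's value by its temporal standard deviation and
#' renormalizes to unit mask mean: the map one would obtain by z-scoring the
#' BOLD signal before the ALFF computation and then normalizing. Equals the
#' plain normalized map if and only if sigma is constant across voxels.
#'
#' @param map A [voxel_map()] of an ALFF-type metric.
#' @param sigma Per-voxel temporal standard deviations aligned with `map`
#'   (from [voxel_sigma()]).
#' @return A [voxel_map()], `metric_name` suffixed `"_norm_z"`.
#' @export
znorm_map <- function(map, sigma) {
  stopifnot(inherits(map, "voxel_map"))
  sigma <- as.numeric(sigma)
  if (length(sigma) != length(map$values))
    stop("sigma length ", length(sigma), " does not match map length ",
         length(map$values))
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  out <- map
  out$values <- map$values / sigma
  out <- normalize_map(out)
  base <- sub("_norm$", "", map$metric_name)
  out$metric_name <- paste0(base, "_norm_z")
  out
}

#' Shared variance between two voxel maps
#'
#' The squared Pearson correlation across voxels: the fraction of variance
#' the two maps share. Used to quantify how much z-scoring disrupts the
#' normalized ALFF distribution.
#'
#' @param map_a,map_b Aligned [voxel_map()]s with at least 3 voxels each.
#' @return A single number in `[0, 1]`.
#' @export
shared_variance <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "voxel_map"), inherits(map_b, "voxel_map"))
  check_aligned(map_a, map_b)
  if (length(map_a$values) < 3L) stop("need at least 3 voxels")
  if (stats::sd(map_a$values) == 0 || stats::sd(map_b$values) == 0)
    stop("shared variance undefined for a constant map")
  stats::cor(map_a$values, map_b$values)^2
}
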