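#' Construct a BOLD series object
#'
#' A `bold_series` holds the masked voxel-by-time matrix extracted from a 4D
#' BOLD acquisition, together with the repetition time and enough spatial
#' bookkeeping to write voxelwise results back into volume space.
#'
#' @param data Numeric matrix, M voxels x N timepoints, in arbitrary scanner
#'   units.
#' @param tr Repetition time in seconds (> 0).
#' @param voxel_index Integer matrix M x 3 of 1-based (i, j, k) coordinates of
#'   the retained voxels, or `NULL` for series with no spatial provenance
#'   (e.g. purely synthetic test signals).
#' @param spatial_ref List with elements `dim` (3D grid dimensions) and
#'   `affine` (4 x 4 voxel-to-world matrix), or `NULL`.
#' @param demeaned Logical; whether each row has had its temporal mean removed.
#' @param voxel_means Numeric vector of per-voxel temporal means of the raw
#'   (pre-demeaning) signal; kept because the mean BOLD intensity diagnostics
#'   need the raw intensities that demeaning destroys.
#' @param n_dropped Number of in-mask voxels dropped for zero temporal
#'   variance during reading.
#'
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, tr, voxel_index = NULL, spatial_ref = NULL,
                        demeaned = FALSE, voxel_means = NULL, n_dropped = 0L) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  storage.mode(data) <- "double"
  if (nrow(data) < 1L) stop("bold_series needs at least one voxel")
  if (ncol(data) < 8L) stop("bold_series needs at least 8 timepoints, got ", ncol(data))
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("tr must be a single positive number (seconds)")
  if (!is.null(voxel_index)) {
    voxel_index <- as.matrix(voxel_index)
    if (nrow(voxel_index) != nrow(data) || ncol(voxel_index) != 3L)
      stop("voxel_index must be an M x 3 matrix matching data")
    if (!is.null(spatial_ref)) {
      d <- spatial_ref$dim
      if (any(voxel_index < 1L) || any(voxel_index > rep(d, each = nrow(voxel_index))))
        stop("voxel_index coordinates fall outside the source volume shape")
    }
  }
  if (is.null(voxel_means)) voxel_means <- rowMeans(data)
  structure(
    list(data = data, tr = tr, voxel_index = voxel_index,
         spatial_ref = spatial_ref, demeaned = isTRUE(demeaned),
         voxel_means = as.numeric(voxel_means), n_dropped = as.integer(n_dropped)),
    class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %d voxels x %d timepoints, TR = %g s%s\n",
              nrow(x$data), ncol(x$data), x$tr,
              if (x$demeaned) ", demeaned" else ""))
  if (x$n_dropped > 0L)
    cat(sprintf("  (%d zero-variance in-mask voxels were dropped at read)\n", x$n_dropped))
  invisible(x)
}

#' Number of voxels / timepoints of a BOLD series
#' @param series A `bold_series`.
#' @return Integer count.
#' @export
n_voxels <- function(series) nrow(series$data)

#' @rdname n_voxels
#' @export
n_timepoints <- function(series) ncol(series$data)

#' Construct a voxelwise metric map
#'
#' One scalar per retained voxel, labelled with the metric it carries
#' (`amALFF`, `qmALFF`, `amfALFF`, `qmfALFF`, `MBI`, or a `_norm` /
#' `_norm_z` derivative).
#'
#' @param values Numeric vector, one value per retained voxel.
#' @param metric_name Character label for the metric.
#' @param voxel_index,spatial_ref Spatial bookkeeping inherited from the
#'   source [bold_series()]; may be `NULL` for in-memory use.
#' @return An object of class `voxel_map`.
#' @export
voxel_map <- function(values, metric_name, voxel_index = NULL, spatial_ref = NULL) {
  values <- as.numeric(values)
  if (!is.null(voxel_index) && nrow(as.matrix(voxel_index)) != length(values))
    stop("voxel_index rows must match length(values)")
  structure(
    list(values = values, metric_name = as.character(metric_name)[1L],
         voxel_index = voxel_index, spatial_ref = spatial_ref),
    class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  cat(sprintf("<voxel_map> %s: %d voxels, mean %.6g, range [%.6g, %.6g]\n",
              x$metric_name, length(x$values), mean(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

# Derive a voxel_map from a series, reusing its spatial provenance.
map_from_series <- function(series, values, metric_name) {
  voxel_map(values, metric_name,
            voxel_index = series$voxel_index,
            spatial_ref = series$spatial_ref)
}

# Shared check that two maps (or a map and a sigma vector) are alignable.
check_aligned <- function(a, b, what = "maps") {
  if (length(a$values) != length(b$values))
    stop("misaligned ", what, ": ", length(a$values), " vs ", length(b$values), " voxels")
  invisible(TRUE)
}
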