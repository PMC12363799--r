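#' Read a 4D BOLD volume and a 3D mask into a voxel-by-time matrix
#'
#' Extracts the time series of every voxel where `mask > 0` into the rows of
#' a [bold_series()]. Rows follow the sorted flattened index of the volume in
#' the array's native (column-major) order, so repeated reads of the same
#' files yield bit-identical objects. In-mask voxels with zero temporal
#' variance are dropped (every downstream estimator divides by a spectral or
#' RMS quantity that would be zero for them); the count of dropped voxels is
#' recorded in the returned object and reported with a message.
#'
#' @param bold_path Path to a 4D NIfTI (.nii / .nii.gz) BOLD volume.
#' @param mask_path Path to a 3D NIfTI mask on the identical spatial grid.
#' @param tr Optional repetition time override in seconds. When absent, TR is
#'   taken from the header's 4th pixdim; a missing/non-positive header value
#'   is a hard error, and a header value of exactly 1 (a common placeholder)
#'   produces a warning.
#' @param verbose Emit a message with the dropped-voxel count.
#'
#' @return A [bold_series()] with `demeaned = FALSE`.
#' @export
read_bold <- function(bold_path, mask_path, tr = NULL, verbose = TRUE) {
  bold <- RNifti::readNifti(bold_path)
  mask <- RNifti::readNifti(mask_path)
  db <- dim(bold)
  dm <- dim(mask)
  if (length(db) != 4L)
    stop("BOLD volume must be 4D, got dimensions [", paste(db, collapse = " x "), "]")
  if (length(dm) != 3L || !all(db[1:3] == dm))
    stop("spatial grid mismatch: BOLD is [", paste(db[1:3], collapse = " x "),
         "] but mask is [", paste(dm, collapse = " x "), "]")

  if (is.null(tr)) {
    hdr <- RNifti::niftiHeader(bold)
    tr <- hdr$pixdim[5L]
    if (is.na(tr) || tr <= 0)
      stop("TR not recoverable from the BOLD header (pixdim[4] = ", tr,
           "); supply tr explicitly")
    if (tr == 1)
      warning("header TR is exactly 1 s, a common placeholder; ",
              "supply tr explicitly if this is not the true repetition time")
  }

  nvol <- db[4L]
  flat <- which(as.vector(mask) > 0)          # sorted flat indices, native order
  if (length(flat) == 0L) stop("mask selects no voxels")
  dat <- matrix(as.vector(bold), nrow = prod(db[1:3]), ncol = nvol)[flat, , drop = FALSE]

  mu <- rowMeans(dat)
  ss <- rowSums((dat - mu)^2)
  keep <- ss > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    if (verbose)
      message(n_dropped, " in-mask voxel(s) with zero temporal variance dropped")
    flat <- flat[keep]
    dat <- dat[keep, , drop = FALSE]
    mu <- mu[keep]
  }
  if (nrow(dat) == 0L) stop("all in-mask voxels have zero temporal variance")

  idx <- arrayInd(flat, db[1:3])
  ref <- list(dim = db[1:3],
              affine = unclass(RNifti::xform(bold)),
              header = RNifti::niftiHeader(bold))
  bold_series(dat, tr = tr, voxel_index = idx, spatial_ref = ref,
              demeaned = FALSE, voxel_means = mu, n_dropped = n_dropped)
}

#' Write a voxelwise metric map to a NIfTI volume
#'
#' Values are placed at the map's voxel coordinates inside the source grid;
#' voxels outside the mask support are written as `NaN` (or 0 under
#' `background = 0`). Output is float32 by the usual neuroimaging convention;
#' `datatype = "double"` gives a bit-exact float64 round trip. The metric
#' label is stored in the header `descrip` field.
#'
#' @param map A [voxel_map()] carrying `voxel_index` and `spatial_ref`.
#' @param path Output file path (.nii or .nii.gz).
#' @param background Fill value for out-of-mask voxels: `NaN` (default) or 0.
#' @param datatype `"float"` (32-bit, default) or `"double"` (64-bit).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, background = NaN, datatype = c("float", "double")) {
  datatype <- match.arg(datatype)
  if (is.null(map$spatial_ref) || is.null(map$voxel_index))
    stop("map carries no spatial reference; cannot place values in a volume")
  d <- map$spatial_ref$dim
  idx <- as.matrix(map$voxel_index)
  if (nrow(idx) != length(map$values))
    stop("map has ", length(map$values), " values but ", nrow(idx), " voxel coordinates")
  arr <- array(as.numeric(background), dim = d)
  arr[idx] <- map$values
  img <- RNifti::asNifti(arr, reference = list(descrip = map$metric_name))
  aff <- map$spatial_ref$affine
  if (!is.null(aff)) {
    RNifti::`sform<-`(img, structure(aff, code = 2L))
    RNifti::`qform<-`(img, structure(aff, code = 2L))
  }
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a metric map back from a NIfTI volume
#'
#' Inverse of [write_map()]: extracts the values at the given mask support.
#'
#' @param path NIfTI file written by [write_map()].
#' @param voxel_index M x 3 coordinates of the mask support.
#' @param metric_name Optional label; defaults to the header `descrip`.
#' @return A [voxel_map()].
#' @export
read_map <- function(path, voxel_index, metric_name = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(metric_name)) metric_name <- RNifti::niftiHeader(img)$descrip
  if (!nzchar(metric_name)) metric_name <- "map"
  idx <- as.matrix(voxel_index)
  ref <- list(dim = dim(img)[1:3], affine = unclass(RNifti::xform(img)))
  voxel_map(img[idx], metric_name, voxel_index = idx, spatial_ref = ref)
}
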