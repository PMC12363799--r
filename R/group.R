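#' Compute all four ALFF maps for one subject
#'
#' Convenience wrapper: demeans, takes the amplitude spectrum, and evaluates
#' amALFF, qmALFF, amfALFF and qmfALFF for the given band.
#'
#' @param series A [bold_series()].
#' @param band A [band_spec()].
#' @return Named list of four [voxel_map()]s.
#' @export
alff_maps <- function(series, band = band_spec()) {
  dm <- demean(series)
  sp <- amplitude_spectrum(dm)
  idx <- band_indices(band, n_timepoints(dm), dm$tr)
  list(amALFF = am_alff(sp, idx),
       qmALFF = qm_alff_freq(sp, idx),
       amfALFF = am_falff(sp, idx),
       qmfALFF = qm_falff_freq(sp, idx))
}

#' Subject-level metric table
#'
#' One row per subject: MBI plus the mask means of the four ALFF maps —
#' the quantities whose pairwise correlations are examined at the subject
#' level.
#'
#' @param subjects A list of [bold_series()] on a common mask.
#' @param band A [band_spec()].
#' @return Data frame with columns `subject`, `MBI`, `amALFF`, `qmALFF`,
#'   `amfALFF`, `qmfALFF`.
#' @export
subject_table <- function(subjects, band = band_spec()) {
  stopifnot(length(subjects) >= 1L)
  check_same_support(subjects)
  rows <- lapply(seq_along(subjects), function(s) {
    m <- alff_maps(subjects[[s]], band)
    data.frame(subject = s,
               MBI = mbi_subject(subjects[[s]]),
               amALFF = mean(m$amALFF$values),
               qmALFF = mean(m$qmALFF$values),
               amfALFF = mean(m$amfALFF$values),
               qmfALFF = mean(m$qmfALFF$values))
  })
  do.call(rbind, rows)
}

#' Voxel-level metric table
#'
#' One row per voxel: across-subject mean BOLD intensity, across-subject
#' means of the per-subject *normalized* amALFF and qmALFF maps, and
#' across-subject means of the fALFF maps (which need no normalization).
#'
#' @inheritParams subject_table
#' @return Data frame with columns `voxel`, `MBI`, `amALFF_norm`,
#'   `qmALFF_norm`, `amfALFF`, `qmfALFF`.
#' @export
voxel_table <- function(subjects, band = band_spec()) {
  stopifnot(length(subjects) >= 1L)
  check_same_support(subjects)
  M <- n_voxels(subjects[[1L]])
  acc <- list(amALFF_norm = 0, qmALFF_norm = 0, amfALFF = 0, qmfALFF = 0)
  for (s in subjects) {
    m <- alff_maps(s, band)
    acc$amALFF_norm <- acc$amALFF_norm + normalize_map(m$amALFF)$values
    acc$qmALFF_norm <- acc$qmALFF_norm + normalize_map(m$qmALFF)$values
    acc$amfALFF <- acc$amfALFF + m$amfALFF$values
    acc$qmfALFF <- acc$qmfALFF + m$qmfALFF$values
  }
  ns <- length(subjects)
  data.frame(voxel = seq_len(M),
             MBI = mbi_voxel(subjects)$values,
             amALFF_norm = acc$amALFF_norm / ns,
             qmALFF_norm = acc$qmALFF_norm / ns,
             amfALFF = acc$amfALFF / ns,
             qmfALFF = acc$qmfALFF / ns)
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Pearson r (with the standard two-sided t-test p-value, no multiplicity
#' correction) between every pair of metric columns. Constant columns yield
#' `NA` entries with a warning rather than an error.
#'
#' @param table A metric table from [subject_table()] or [voxel_table()]
#'   (or any data frame; `subject`, `voxel` and `cluster` columns are
#'   excluded automatically).
#' @param by_cluster If `TRUE` and `table` has a `cluster` column, compute a
#'   separate matrix within each cluster and return a named list.
#' @return An object of class `alff_cormat`: list with matrices `r` and `p`
#'   and the sample size `n` — or a named list of such objects when
#'   `by_cluster = TRUE`.
#' @export
correlation_matrix <- function(table, by_cluster = FALSE) {
  if (by_cluster) {
    if (is.null(table$cluster)) stop("by_cluster = TRUE needs a 'cluster' column")
    return(lapply(split(table, table$cluster),
                  function(tb) correlation_matrix(tb, by_cluster = FALSE)))
  }
  cols <- setdiff(names(table)[vapply(table, is.numeric, logical(1L))],
                  c("subject", "voxel"))
  x <- as.matrix(table[cols])
  if (nrow(x) < 3L) stop("need at least 3 rows for a correlation matrix")
  p <- ncol(x)
  r_mat <- diag(1, p); p_mat <- matrix(0, p, p)
  dimnames(r_mat) <- dimnames(p_mat) <- list(cols, cols)
  const <- apply(x, 2L, stats::sd) == 0
  if (any(const))
    warning("constant column(s) ", paste(cols[const], collapse = ", "),
            ": correlations reported as NA")
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    if (const[i] || const[j]) {
      r_mat[i, j] <- r_mat[j, i] <- NA_real_
      p_mat[i, j] <- p_mat[j, i] <- NA_real_
    } else {
      ct <- stats::cor.test(x[, i], x[, j], method = "pearson")
      r_mat[i, j] <- r_mat[j, i] <- unname(ct$estimate)
      p_mat[i, j] <- p_mat[j, i] <- ct$p.value
    }
  }
  structure(list(r = r_mat, p = p_mat, n = nrow(x)), class = "alff_cormat")
}

#' @export
print.alff_cormat <- function(x, digits = 3, ...) {
  cat(sprintf("<alff_cormat> Pearson r over %d rows\n", x$n))
  print(round(x$r, digits))
  invisible(x)
}

#' Write a correlation matrix (r and p) as CSV
#'
#' @param cm An `alff_cormat`.
#' @param path Output CSV path; rows are metric pairs with r and p columns.
#' @return `path`, invisibly.
#' @export
write_cormat <- function(cm, path) {
  stopifnot(inherits(cm, "alff_cormat"))
  nm <- rownames(cm$r)
  pairs <- which(upper.tri(cm$r), arr.ind = TRUE)
  df <- data.frame(metric_a = nm[pairs[, 1L]], metric_b = nm[pairs[, 2L]],
                   r = cm$r[pairs], p = cm$p[pairs], n = cm$n)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot a correlation matrix as a shaded grid
#'
#' Base-graphics image of the r matrix with the coefficients printed in each
#' cell; a quick visual twin of the usual correlation-matrix figure.
#'
#' @param x An `alff_cormat`.
#' @param main Plot title.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.alff_cormat <- function(x, main = "Pearson correlation", ...) {
  r <- x$r
  p <- ncol(r)
  pal <- grDevices::hcl.colors(21L, "Blue-Red 3")
  graphics::image(seq_len(p), seq_len(p), t(r[p:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "", main = main)
  graphics::axis(1L, at = seq_len(p), labels = colnames(r), las = 2, cex.axis = 0.8)
  graphics::axis(2L, at = seq_len(p), labels = rev(rownames(r)), las = 2, cex.axis = 0.8)
  for (i in seq_len(p)) for (j in seq_len(p))
    graphics::text(j, p - i + 1L, sprintf("%.2f", r[i, j]), cex = 0.8)
  invisible(x)
}

#' Cluster subjects (or voxels) by mean BOLD intensity
#'
#' Deterministic 1-D k-means on the MBI column: initial centers are the
#' `(2i - 1)/(2k)` quantiles of MBI, and cluster labels are ordered by
#' ascending cluster mean (`l`, `m`, `h` for k = 3). A convenience for
#' cohorts whose MBI distribution is multimodal, e.g. after scanner software
#' changes; the clustering method itself is a pragmatic choice, not a
#' modelling claim.
#'
#' @param table A metric table with an `MBI` column.
#' @param k Number of clusters.
#' @return `table` with a `cluster` factor column appended.
#' @export
cluster_mbi <- function(table, k = 3L) {
  if (is.null(table$MBI)) stop("table has no MBI column")
  mbi <- table$MBI
  if (k < 1L) stop("k must be >= 1")
  if (k > length(unique(mbi)))
    stop("k = ", k, " exceeds the number of distinct MBI values (",
         length(unique(mbi)), ")")
  if (k == 1L) {
    table$cluster <- factor(rep("c1", length(mbi)))
    return(table)
  }
  centers <- matrix(unname(stats::quantile(mbi, probs = (2 * seq_len(k) - 1) / (2 * k),
                                           type = 7)), ncol = 1L)
  if (anyDuplicated(centers)) centers <- matrix(sort(unique(mbi))[
    round(seq(1L, length(unique(mbi)), length.out = k))], ncol = 1L)
  km <- stats::kmeans(matrix(mbi, ncol = 1L), centers = centers)
  ord <- order(km$centers[, 1L])
  labels <- if (k == 3L) c("l", "m", "h") else paste0("c", seq_len(k))
  relab <- integer(k); relab[ord] <- seq_len(k)
  table$cluster <- factor(labels[relab[km$cluster]], levels = labels)
  table
}
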