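# Functional connectivity: sphere-based ROI time-series extraction and
# partial-correlation networks (each edge conditions on all remaining nodes).

#' Extract mean ROI time series from a 4-D volume
#'
#' For each ROI the mean signal over all voxels whose center lies within the
#' ROI sphere (Euclidean distance in mm, inclusive boundary) is computed at
#' every timepoint.
#'
#' @param volume4d 4-D numeric array `[x, y, z, t]`, or an `RNifti` image
#'   (in which case the affine is read from the header).
#' @param atlas An `roi_atlas`.
#' @param affine 4 x 4 voxel-to-mm matrix (0-based indices); required for a
#'   plain array.
#' @return A `timeseries_panel`: T x N matrix, columns in atlas order.
#' @export
extract_roi_timeseries <- function(volume4d, atlas, affine = NULL) {
  if (inherits(volume4d, "niftiImage")) {
    affine <- structure_affine(volume4d)
    volume4d <- as_plain_array(as.array(volume4d))
  }
  if (!is.array(volume4d) || length(dim(volume4d)) != 4L) {
    stop("`volume4d` must be a 4-D array or NIfTI image.", call. = FALSE)
  }
  if (is.null(affine)) {
    stop("`affine` is required when `volume4d` is a plain array.",
         call. = FALSE)
  }
  d <- dim(volume4d)
  nt <- d[4]
  flat <- matrix(volume4d, prod(d[1:3]), nt)
  ijk <- as.matrix(expand.grid(x = seq_len(d[1]) - 1L,
                               y = seq_len(d[2]) - 1L,
                               z = seq_len(d[3]) - 1L))
  pts <- cbind(ijk, 1) %*% t(affine)
  pts <- pts[, 1:3, drop = FALSE]
  centers <- atlas_centers(atlas)
  out <- matrix(NA_real_, nt, nrow(atlas))
  colnames(out) <- atlas$name
  for (r in seq_len(nrow(atlas))) {
    d2 <- (pts[, 1] - centers[r, 1])^2 + (pts[, 2] - centers[r, 2])^2 +
      (pts[, 3] - centers[r, 3])^2
    inside <- d2 <= atlas$radius_mm[r]^2
    if (!any(inside)) {
      stop("ROI \"", atlas$name[r], "\" contains no voxel center.",
           call. = FALSE)
    }
    out[, r] <- colMeans(flat[inside, , drop = FALSE])
  }
  structure(out, node_order = atlas$name,
            class = c("timeseries_panel", "matrix", "array"))
}

#' Partial-correlation connectivity matrix
#'
#' Entry (i, j) is the correlation between nodes i and j conditional on all
#' remaining nodes, obtained from the (optionally ridge-regularized) inverse
#' sample covariance Omega as `-Omega_ij / sqrt(Omega_ii * Omega_jj)`;
#' symmetric with zero diagonal.
#'
#' @param panel T x N numeric matrix of ROI time series (a
#'   `timeseries_panel` or plain matrix with column names).
#' @param ridge Non-negative ridge added to the sample covariance as
#'   `ridge * mean(diag(S)) * I` before inversion (default 0). Required when
#'   T <= N or the covariance is singular.
#' @return A `connectivity_matrix` (functional, signed).
#' @export
partial_correlation_matrix <- function(panel, ridge = 0) {
  x <- as.matrix(panel)
  n <- ncol(x)
  t_len <- nrow(x)
  stopifnot(ridge >= 0)
  if (anyNA(x)) stop("Time-series panel contains missing values.",
                     call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("Column(s) with zero variance: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  if (t_len <= n && ridge == 0) {
    stop("T (", t_len, ") must exceed the number of nodes (", n,
         ") when ridge = 0; supply a positive `ridge` for short panels.",
         call. = FALSE)
  }
  s <- stats::cov(x)
  if (ridge > 0) s <- s + ridge * mean(diag(s)) * diag(n)
  omega <- tryCatch(
    chol2inv(chol(s)),
    error = function(e) {
      stop("Sample covariance is not invertible; supply a positive `ridge`.",
           call. = FALSE)
    }
  )
  p <- precision_to_partial(omega)
  nodes <- colnames(x)
  if (is.null(nodes)) nodes <- paste0("node_", seq_len(n))
  connectivity_matrix(p, "functional", "signed", node_order = nodes)
}

#' Map signed partial correlations to non-negative edge weights
#'
#' `zero_negatives` (default) sets negative entries to zero, keeping the
#' positive-coupling backbone that shortest-path metrics require; `absolute`
#' keeps magnitudes regardless of sign.
#'
#' @param signed A signed functional `connectivity_matrix`.
#' @param mode `"zero_negatives"` or `"absolute"`.
#' @return A `connectivity_matrix` (functional, weighted).
#' @export
weight_functional <- function(signed, mode = c("zero_negatives", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(inherits(signed, "connectivity_matrix"))
  v <- unclass_matrix(signed)
  v <- if (mode == "zero_negatives") pmax(v, 0) else abs(v)
  connectivity_matrix(v, matrix_modality(signed), "weighted",
                      node_order = attr(signed, "node_order"))
}

#' Binarize a weighted connectivity matrix
#'
#' Every strictly non-zero weight becomes 1, zeros stay 0. An optional
#' magnitude threshold (default 0, i.e. the strict non-zero rule) lets users
#' sparsify near-complete graphs that arise from continuous edge weights:
#' entries at or below the threshold are set to 0.
#'
#' @param weighted A non-negative `connectivity_matrix`.
#' @param threshold Magnitude at or below which entries are treated as absent
#'   (default 0).
#' @return A `connectivity_matrix` of the same modality, binary weighting.
#' @export
binarize <- function(weighted, threshold = 0) {
  stopifnot(inherits(weighted, "connectivity_matrix"), threshold >= 0)
  v <- unclass_matrix(weighted)
  if (any(v < 0)) {
    stop("Binarization expects non-negative weights; apply ",
         "weight_functional() first.", call. = FALSE)
  }
  b <- (v > threshold) * 1
  connectivity_matrix(b, matrix_modality(weighted), "binary",
                      node_order = attr(weighted, "node_order"))
}
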