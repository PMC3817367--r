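# Structural connectivity from streamlines: streamline-count and FA-weighted
# matrices over the atlas spheres, plus optional normalization.

# For each streamline, the set of ROI indices with at least one vertex inside
# the ROI sphere (pass-through assignment, inclusive boundary).
streamline_roi_hits <- function(coords, centers, radii) {
  hits <- logical(nrow(centers))
  for (r in seq_len(nrow(centers))) {
    d2 <- (coords[, 1] - centers[r, 1])^2 + (coords[, 2] - centers[r, 2])^2 +
      (coords[, 3] - centers[r, 3])^2
    hits[r] <- any(d2 <= radii[r]^2)
  }
  which(hits)
}

#' Streamline-count structural connectivity matrix
#'
#' Entry (i, j) counts the streamlines that pass through both ROI spheres
#' (any vertex within radius of either center); a streamline traversing k
#' spheres increments all k(k-1)/2 pairs. Symmetric, zero diagonal.
#'
#' @param streamlines A `streamline_set`.
#' @param atlas An `roi_atlas` in the same mm space.
#' @return A `connectivity_matrix` (structural, weighted).
#' @export
count_matrix <- function(streamlines, atlas) {
  stopifnot(inherits(streamlines, "streamline_set"))
  n <- nrow(atlas)
  centers <- atlas_centers(atlas)
  m <- matrix(0, n, n)
  for (coords in streamlines$coords) {
    idx <- streamline_roi_hits(coords, centers, atlas$radius_mm)
    if (length(idx) >= 2L) {
      pairs <- utils::combn(idx, 2L)
      for (q in seq_len(ncol(pairs))) {
        i <- pairs[1L, q]; j <- pairs[2L, q]
        m[i, j] <- m[i, j] + 1
        m[j, i] <- m[j, i] + 1
      }
    }
  }
  connectivity_matrix(m, "structural", "weighted", node_order = atlas$name)
}

#' FA-weighted structural connectivity matrix
#'
#' Entry (i, j) is the mean, over all streamlines connecting ROIs i and j, of
#' each streamline's mean interpolated FA sampled at its vertices; 0 where no
#' streamline connects the pair.
#'
#' @param streamlines A `streamline_set`.
#' @param volume The `tensor_volume` the streamlines were tracked through.
#' @param atlas An `roi_atlas`.
#' @return A `connectivity_matrix` (structural, weighted).
#' @export
fa_weight_matrix <- function(streamlines, volume, atlas) {
  stopifnot(inherits(streamlines, "streamline_set"),
            inherits(volume, "tensor_volume"))
  n <- nrow(atlas)
  centers <- atlas_centers(atlas)
  total <- matrix(0, n, n)
  count <- matrix(0, n, n)
  for (coords in streamlines$coords) {
    idx <- streamline_roi_hits(coords, centers, atlas$radius_mm)
    if (length(idx) < 2L) next
    fa <- fa_at_points(volume, coords)
    mfa <- mean(fa, na.rm = TRUE)
    pairs <- utils::combn(idx, 2L)
    for (q in seq_len(ncol(pairs))) {
      i <- pairs[1L, q]; j <- pairs[2L, q]
      total[i, j] <- total[i, j] + mfa
      total[j, i] <- total[j, i] + mfa
      count[i, j] <- count[i, j] + 1
      count[j, i] <- count[j, i] + 1
    }
  }
  m <- ifelse(count > 0, total / pmax(count, 1), 0)
  connectivity_matrix(m, "structural", "weighted", node_order = atlas$name)
}

#' Normalize a structural connectivity matrix
#'
#' `raw` returns the input unchanged; `total_fraction` divides every entry by
#' the sum over unordered pairs, so edge weights sum to 1 across the upper
#' triangle.
#'
#' @param matrix A non-negative `connectivity_matrix`.
#' @param mode `"raw"` or `"total_fraction"`.
#' @return A `connectivity_matrix`.
#' @export
normalize_structural <- function(matrix, mode = c("raw", "total_fraction")) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "connectivity_matrix"))
  if (mode == "raw") return(matrix)
  tot <- sum(matrix[upper.tri(matrix)])
  if (tot == 0) {
    stop("Cannot total-fraction normalize a zero matrix.", call. = FALSE)
  }
  connectivity_matrix(unclass_matrix(matrix) / tot, matrix_modality(matrix),
                      "weighted", node_order = attr(matrix, "node_order"))
}
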