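# Deterministic streamline tractography over a tensor volume: seeds on a
# uniform mm grid restricted to voxels above the FA threshold, Euler
# propagation in both directions along the trilinearly interpolated tensor's
# principal eigenvector, termination on low FA, sharp turns, volume exit, or
# the step cap.

#' Tractography parameters
#'
#' @param seed_spacing_mm Isotropic seed-grid spacing, mm (default 2).
#' @param step_size_mm Euler step length, mm (default 1).
#' @param fa_threshold Propagation stops where interpolated FA falls below
#'   this value (default 0.2); seeding is restricted to voxels at or above it.
#' @param angle_threshold_deg Propagation stops when the turn between
#'   consecutive step directions exceeds this angle (default 45, strict).
#' @param max_steps Safety cap on steps per half-track (default 2000).
#' @return A `tracking_params` list.
#' @export
tracking_params <- function(seed_spacing_mm = 2, step_size_mm = 1,
                            fa_threshold = 0.2, angle_threshold_deg = 45,
                            max_steps = 2000L) {
  stopifnot(seed_spacing_mm > 0, step_size_mm > 0, fa_threshold > 0,
            angle_threshold_deg > 0, angle_threshold_deg <= 90,
            max_steps >= 1)
  structure(list(seed_spacing_mm = seed_spacing_mm,
                 step_size_mm = step_size_mm,
                 fa_threshold = fa_threshold,
                 angle_threshold_deg = angle_threshold_deg,
                 max_steps = as.integer(max_steps)),
            class = "tracking_params")
}

#' Track streamlines through a tensor volume
#'
#' Seed points lie on a `seed_spacing_mm` isotropic grid spanning the volume,
#' kept only where the enclosing voxel's FA reaches `fa_threshold`. From each
#' seed the track is propagated in both directions along the principal
#' eigenvector of the trilinearly interpolated tensor with sign continuity
#' (each step's eigenvector is flipped, if needed, toward the previous step
#' direction; the first step uses the seed voxel's eigenvector and its
#' negation for the two halves). Propagation terminates when interpolated FA
#' drops below threshold, the turning angle exceeds the angle threshold, the
#' track leaves the volume, or `max_steps` is reached; the two half-tracks
#' are concatenated through the seed. Single-vertex tracks are dropped.
#'
#' @param volume A `tensor_volume`.
#' @param params A [tracking_params()] list.
#' @return A `streamline_set` tibble with one row per streamline: columns
#'   `streamline_id`, `seed_index`, `n_vertices`, `termination_fwd`,
#'   `termination_bwd`, and list-column `coords` (an n x 3 matrix of mm
#'   vertices). Attributes keep the seed table and parameters. When no voxel
#'   reaches the FA threshold an empty set is returned with a warning.
#' @export
track_streamlines <- function(volume, params = tracking_params()) {
  stopifnot(inherits(volume, "tensor_volume"),
            inherits(params, "tracking_params"))
  d <- dim(volume$tensors)[1:3]
  fa <- fa_volume(volume)
  seeds <- seed_grid(volume, params$seed_spacing_mm)
  keep <- seed_voxel_fa(seeds, volume, fa) >= params$fa_threshold
  seeds <- seeds[keep, , drop = FALSE]
  if (nrow(seeds) == 0L) {
    warning("No seed voxel reaches the FA threshold; returning an empty ",
            "streamline set.", call. = FALSE)
    return(new_streamline_set(list(), integer(), character(), character(),
                              seeds, params))
  }
  res <- cpp_track(volume$tensors, d, volume$affine, seeds,
                   params$step_size_mm, params$fa_threshold,
                   params$angle_threshold_deg, params$max_steps)
  new_streamline_set(res$streamlines, res$seed_index, res$termination_fwd,
                     res$termination_bwd, seeds, params)
}

new_streamline_set <- function(lines, seed_index, term_fwd, term_bwd,
                               seeds, params) {
  out <- tibble::tibble(
    streamline_id = seq_along(lines),
    seed_index = as.integer(seed_index),
    n_vertices = vapply(lines, nrow, integer(1)),
    termination_fwd = as.character(term_fwd),
    termination_bwd = as.character(term_bwd),
    coords = lines
  )
  attr(out, "seeds") <- seeds
  attr(out, "params") <- params
  class(out) <- c("streamline_set", class(out))
  out
}

# uniform mm grid over the volume's bounding box (axis-aligned affine
# assumed for seed placement; tracking itself uses the full affine)
seed_grid <- function(volume, spacing) {
  d <- dim(volume$tensors)[1:3]
  lo <- volume$affine[1:3, 4]
  voxel <- diag(volume$affine)[1:3]
  hi <- lo + (d - 1L) * voxel
  ax <- lapply(1:3, function(i) seq(lo[i], hi[i], by = spacing))
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
}

# FA of the voxel containing each seed (nearest voxel center)
seed_voxel_fa <- function(seeds, volume, fa) {
  inv <- solve(volume$affine)
  v <- cbind(seeds, 1) %*% t(inv)
  idx <- round(v[, 1:3, drop = FALSE])
  d <- dim(fa)
  idx[, 1] <- pmin(pmax(idx[, 1], 0), d[1] - 1L)
  idx[, 2] <- pmin(pmax(idx[, 2], 0), d[2] - 1L)
  idx[, 3] <- pmin(pmax(idx[, 3], 0), d[3] - 1L)
  fa[idx + 1L]
}

#' Interpolated FA along arbitrary mm points
#'
#' Trilinear interpolation of the tensor components followed by
#' eigen-decomposition, matching the values used during tracking. Points
#' outside the volume yield `NA`.
#'
#' @param volume A `tensor_volume`.
#' @param points n x 3 matrix of mm coordinates.
#' @return Numeric vector of FA values.
#' @export
fa_at_points <- function(volume, points) {
  stopifnot(inherits(volume, "tensor_volume"))
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  cpp_fa_at_points(volume$tensors, dim(volume$tensors)[1:3], volume$affine,
                   points)
}

#' Read / write streamlines as a JSON polyline file
#'
#' Plain-text format: a JSON object with `params` and `streamlines`, the
#' latter an array of objects holding `seed_index`, the two termination
#' reasons, and `vertices` (an array of `[x, y, z]` mm triples).
#'
#' @param path File path.
#' @export
read_streamlines_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lines <- lapply(obj$streamlines$vertices, function(v) {
    m <- matrix(as.numeric(v), ncol = 3)
    colnames(m) <- NULL
    m
  })
  p <- obj$params
  params <- tracking_params(p$seed_spacing_mm, p$step_size_mm,
                            p$fa_threshold, p$angle_threshold_deg,
                            p$max_steps)
  new_streamline_set(lines, obj$streamlines$seed_index,
                     obj$streamlines$termination_fwd,
                     obj$streamlines$termination_bwd,
                     seeds = NULL, params = params)
}

#' @rdname read_streamlines_json
#' @param streamlines A `streamline_set`.
#' @export
write_streamlines_json <- function(streamlines, path) {
  p <- attr(streamlines, "params")
  obj <- list(
    params = unclass(p),
    streamlines = list(
      seed_index = streamlines$seed_index,
      termination_fwd = streamlines$termination_fwd,
      termination_bwd = streamlines$termination_bwd,
      vertices = lapply(streamlines$coords, function(m) unname(m))
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
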