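# Fixtures built in code: small atlases, random graphs, synthetic volumes.

# n ROIs placed far apart (cube corners then offset copies), radius 10 mm:
# any bundle between two of them stays > 25 mm away from every other sphere
test_atlas <- function(n, radius_mm = 10, side = 60) {
  corners <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1),
                                   z = c(-1, 1))) * side / 2
  stopifnot(n <= nrow(corners))
  df <- tibble::tibble(name = paste0("roi_", seq_len(n)),
                       x_mm = corners[seq_len(n), 1],
                       y_mm = corners[seq_len(n), 2],
                       z_mm = corners[seq_len(n), 3],
                       radius_mm = radius_mm)
  switchnet:::new_roi_atlas(df)
}

# symmetric random weighted (or binary) graph, zero diagonal
random_graph <- function(n, p_edge = 0.4, weighted = TRUE) {
  m <- matrix(0, n, n)
  up <- upper.tri(m)
  edges <- stats::runif(sum(up)) < p_edge
  w <- if (weighted) stats::runif(sum(up), 0.1, 1) else 1
  m[up] <- edges * w
  m <- m + t(m)
  m
}

# streamline_set from a plain list of vertex matrices
make_streamline_set <- function(lines) {
  switchnet:::new_streamline_set(
    lines, seq_along(lines),
    rep("max_steps", length(lines)), rep("max_steps", length(lines)),
    seeds = NULL, params = tracking_params())
}

# uniform tensor field with the principal axis along `axis`
uniform_volume <- function(dim = c(41L, 11L, 11L), voxel = 1,
                           axis = c(1, 0, 0),
                           lambda = c(1.7, 0.2, 0.2) * 1e-3,
                           origin = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  comp <- switchnet:::fiber_tensor(axis, lambda)
  tensors <- array(rep(comp, each = prod(dim)), c(dim, 6L))
  affine <- diag(c(rep(voxel, 3), 1))
  affine[1:3, 4] <- origin
  tensor_volume(tensors, affine)
}

# post-hoc audit: step spacing, FA at every vertex, turning angles
audit_streamlines <- function(sl, volume, params) {
  ok_spacing <- TRUE
  max_angle <- 0
  min_fa <- Inf
  for (coords in sl$coords) {
    if (nrow(coords) < 2) next
    steps <- diff(coords)
    lens <- sqrt(rowSums(steps^2))
    ok_spacing <- ok_spacing &&
      all(abs(lens - params$step_size_mm) < 1e-8)
    if (nrow(steps) >= 2) {
      u <- steps / lens
      cosang <- rowSums(u[-nrow(u), , drop = FALSE] *
                        u[-1, , drop = FALSE])
      cosang <- pmin(pmax(cosang, -1), 1)
      max_angle <- max(max_angle, max(acos(cosang)) * 180 / pi)
    }
    fa <- fa_at_points(volume, coords)
    min_fa <- min(min_fa, min(fa, na.rm = TRUE))
  }
  list(ok_spacing = ok_spacing, max_angle = max_angle, min_fa = min_fa)
}

# random well-separated bundle configuration on the cube-corner atlas:
# node-disjoint pairs whose tube axes stay far apart (cube space diagonals
# intersect at the center, so pairings are rejection-sampled on a minimum
# segment-to-segment distance)
random_phantom_config <- function(n_bundles = NULL, min_sep = 15) {
  atlas <- test_atlas(8)
  centers <- as.matrix(atlas[, c("x_mm", "y_mm", "z_mm")])
  if (is.null(n_bundles)) n_bundles <- sample(1:4, 1)
  seg_points <- function(b) {
    t <- seq(0, 1, length.out = 40)
    outer(1 - t, centers[b[1], ]) + outer(t, centers[b[2], ])
  }
  repeat {
    nodes <- sample(8, 2 * n_bundles)
    bundles <- unname(split(nodes, rep(seq_len(n_bundles), each = 2)))
    pts <- lapply(bundles, seg_points)
    ok <- TRUE
    if (n_bundles >= 2) {
      for (i in seq_len(n_bundles - 1)) {
        for (j in (i + 1):n_bundles) {
          d2 <- outer(rowSums(pts[[i]]^2), rowSums(pts[[j]]^2), `+`) -
            2 * tcrossprod(pts[[i]], pts[[j]])
          if (min(d2) < min_sep^2) ok <- FALSE
        }
      }
    }
    if (ok) break
  }
  adjacency <- matrix(0, 8, 8)
  for (b in bundles) {
    adjacency[b[1], b[2]] <- 1
    adjacency[b[2], b[1]] <- 1
  }
  list(atlas = atlas, bundles = bundles, adjacency = adjacency)
}

# strip class and dimnames so matrices compare directly against plain oracles
unclass_keep_dim <- function(m) {
  m <- unclass(m)
  attributes(m) <- list(dim = dim(m))
  m
}

# wrap a plain symmetric matrix as a connectivity matrix
as_cm_test <- function(m) {
  connectivity_matrix(m, "functional",
                      if (all(m %in% c(0, 1))) "binary" else "weighted")
}
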