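# Diffusion-tensor volume container. Tensors are stored as a 4-D array
# [x, y, z, 6] holding the unique components in order
# Dxx, Dxy, Dxz, Dyy, Dyz, Dzz; the affine maps 0-based voxel indices to mm.

#' Construct a tensor volume
#'
#' @param tensors 4-D numeric array `[nx, ny, nz, 6]`, components ordered
#'   Dxx, Dxy, Dxz, Dyy, Dyz, Dzz.
#' @param affine 4 x 4 matrix mapping 0-based voxel indices (homogeneous) to
#'   mm coordinates.
#' @return A `tensor_volume` object.
#' @export
tensor_volume <- function(tensors, affine) {
  stopifnot(is.array(tensors), length(dim(tensors)) == 4L,
            dim(tensors)[4] == 6L,
            is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(tensors = tensors, affine = affine),
            class = "tensor_volume")
}

#' @export
print.tensor_volume <- function(x, ...) {
  d <- dim(x$tensors)
  cat("<tensor_volume> ", d[1], " x ", d[2], " x ", d[3],
      " voxels, voxel size ",
      paste(signif(abs(diag(x$affine)[1:3]), 3), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Fractional anisotropy of a single diffusion tensor
#'
#' `FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2)) / sqrt(sum(lambda_i^2))`
#' with eigenvalues clamped at zero; the zero tensor is assigned FA 0.
#'
#' @param tensor Symmetric 3 x 3 matrix.
#' @return Scalar in `[0, 1]`.
#' @examples
#' fa_from_tensor(diag(3))           # isotropic -> 0
#' fa_from_tensor(diag(c(1, 0, 0)))  # stick -> 1
#' @export
fa_from_tensor <- function(tensor) {
  stopifnot(is.matrix(tensor), all(dim(tensor) == c(3L, 3L)))
  if (max(abs(tensor - t(tensor))) > 1e-8 * max(1, max(abs(tensor)))) {
    stop("`tensor` must be symmetric.", call. = FALSE)
  }
  lam <- pmax(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values, 0)
  ss <- sum(lam^2)
  if (ss == 0) return(0)
  fa <- sqrt(1.5 * sum((lam - mean(lam))^2) / ss)
  min(fa, 1)
}

#' Per-voxel FA map of a tensor volume
#'
#' @param volume A `tensor_volume`.
#' @return 3-D array of FA values.
#' @export
fa_volume <- function(volume) {
  stopifnot(inherits(volume, "tensor_volume"))
  d <- dim(volume$tensors)
  fa <- cpp_fa_volume(volume$tensors, d[1:3])
  array(fa, d[1:3])
}

#' Build a voxel grid specification enclosing an atlas
#'
#' @param atlas An `roi_atlas`.
#' @param voxel_mm Isotropic voxel size in mm (default 2).
#' @param margin_mm Padding added around the ROI bounding box (default 12;
#'   covers the default 10 mm sphere radius).
#' @return A list with `dim` (3 integers) and `affine` (4 x 4).
#' @export
phantom_grid <- function(atlas, voxel_mm = 2, margin_mm = 12) {
  centers <- atlas_centers(atlas)
  lo <- floor(apply(centers, 2, min) - margin_mm)
  hi <- ceiling(apply(centers, 2, max) + margin_mm)
  dim <- as.integer(ceiling((hi - lo) / voxel_mm)) + 1L
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- lo
  list(dim = dim, affine = affine)
}

#' Simulate a tensor phantom with planted fiber bundles
#'
#' Builds a tensor volume in which straight cylindrical fiber bundles connect
#' the centers of chosen ROI pairs. Voxels whose center lies within
#' `tube_radius_mm` of a bundle axis receive an anisotropic tensor whose
#' principal eigenvector follows the axis (eigenvalues `lambda_fiber`,
#' FA about 0.87 at the defaults); all other voxels receive a near-isotropic
#' background tensor (FA well below the 0.2 tracking threshold, with a small
#' seeded eigenvalue jitter so the background is not perfectly uniform).
#'
#' @param atlas An `roi_atlas`.
#' @param bundles List of length-2 integer vectors (1-based ROI indices), or
#'   a 2-column matrix; may be empty.
#' @param grid Grid specification from [phantom_grid()].
#' @param seed Integer seed for the background jitter.
#' @param tube_radius_mm Bundle radius in mm (default 4).
#' @param lambda_fiber Fiber tensor eigenvalues, principal first
#'   (default `c(1.7, 0.2, 0.2) * 1e-3`).
#' @param lambda_background Isotropic background eigenvalue
#'   (default `0.7e-3`).
#' @param jitter Relative background eigenvalue jitter (default 0.02).
#' @return A list with `volume` (a `tensor_volume`) and `adjacency` (the
#'   planted node x node 0/1 matrix).
#' @export
simulate_tensor_phantom <- function(atlas, bundles, grid = phantom_grid(atlas),
                                    seed = 1, tube_radius_mm = 4,
                                    lambda_fiber = c(1.7, 0.2, 0.2) * 1e-3,
                                    lambda_background = 0.7e-3,
                                    jitter = 0.02) {
  n <- nrow(atlas)
  bundles <- normalize_bundles(bundles, n)
  centers <- atlas_centers(atlas)
  lo <- grid$affine[1:3, 4]
  voxel <- diag(grid$affine)[1:3]
  hi <- lo + (grid$dim - 1L) * voxel
  if (any(t(centers) < lo) || any(t(centers) > hi)) {
    stop("Grid does not enclose all ROI centers.", call. = FALSE)
  }

  d <- grid$dim
  nv <- prod(d)
  # voxel centers in mm
  ijk <- as.matrix(expand.grid(x = seq_len(d[1]) - 1L,
                               y = seq_len(d[2]) - 1L,
                               z = seq_len(d[3]) - 1L))
  pts <- sweep(ijk %*% diag(voxel), 2, lo, `+`)

  withr_seed(seed)
  tensors <- array(0, c(d, 6L))
  eps <- matrix(stats::runif(nv * 3L, -jitter, jitter), nv, 3L)
  tensors[, , , 1L] <- lambda_background * (1 + eps[, 1L])
  tensors[, , , 4L] <- lambda_background * (1 + eps[, 2L])
  tensors[, , , 6L] <- lambda_background * (1 + eps[, 3L])

  adjacency <- matrix(0, n, n, dimnames = list(atlas$name, atlas$name))
  flat <- matrix(tensors, nv, 6L)
  for (b in bundles) {
    a <- centers[b[1L], ]
    z <- centers[b[2L], ]
    u <- z - a
    len <- sqrt(sum(u^2))
    if (len == 0) stop("Bundle endpoints coincide.", call. = FALSE)
    u <- u / len
    w <- sweep(pts, 2, a, `-`)
    t_along <- pmin(pmax(w %*% u, 0), len)
    perp <- w - tcrossprod(t_along, u)
    inside <- rowSums(perp^2) <= tube_radius_mm^2
    dt <- fiber_tensor(u, lambda_fiber)
    flat[inside, ] <- matrix(dt, sum(inside), 6L, byrow = TRUE)
    adjacency[b[1L], b[2L]] <- 1
    adjacency[b[2L], b[1L]] <- 1
  }
  tensors <- array(flat, c(d, 6L))
  list(volume = tensor_volume(tensors, grid$affine), adjacency = adjacency)
}

# Unique upper-triangle components (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz) of the
# cylindrically symmetric tensor (l1 - l2) uu' + l2 I.
fiber_tensor <- function(u, lambda) {
  m <- (lambda[1] - lambda[2]) * tcrossprod(u) + lambda[2] * diag(3)
  c(m[1, 1], m[1, 2], m[1, 3], m[2, 2], m[2, 3], m[3, 3])
}

normalize_bundles <- function(bundles, n) {
  if (is.matrix(bundles)) {
    bundles <- lapply(seq_len(nrow(bundles)), function(i) bundles[i, ])
  }
  if (length(bundles) == 0L) return(list())
  lapply(bundles, function(b) {
    b <- as.integer(b)
    if (length(b) != 2L || anyNA(b) || any(b < 1L) || any(b > n) ||
        b[1L] == b[2L]) {
      stop("Each bundle must be a pair of distinct ROI indices in 1..", n,
           ".", call. = FALSE)
    }
    b
  })
}

#' Read / write a tensor volume as NIfTI
#'
#' 4-D NIfTI with 6 volumes holding the unique tensor components in order
#' Dxx, Dxy, Dxz, Dyy, Dyz, Dzz; the image affine carries the voxel-to-mm
#' mapping.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @export
read_tensor_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as_plain_array(as.array(img))
  if (length(dim(arr)) != 4L || dim(arr)[4] != 6L) {
    stop("Expected a 4-D NIfTI with 6 tensor-component volumes.",
         call. = FALSE)
  }
  tensor_volume(arr, structure_affine(img))
}

#' @rdname read_tensor_nifti
#' @param volume A `tensor_volume`.
#' @export
write_tensor_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$tensors)
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

as_plain_array <- function(arr) {
  a <- unclass(arr)
  attributes(a) <- list(dim = dim(a))
  a
}

structure_affine <- function(img) {
  aff <- RNifti::xform(img)
  m <- matrix(as.numeric(aff), 4L, 4L)
  dimnames(m) <- NULL
  m
}
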