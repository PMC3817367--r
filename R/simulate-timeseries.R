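# Multivariate-normal ROI time-series generator with a planted precision
# (inverse covariance) matrix, so the ground-truth partial correlations are
# known in closed form: r_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj).

#' Default control-group precision matrix
#'
#' A deterministic sparse precision (inverse covariance) matrix over the atlas
#' nodes: unit diagonal, with negative off-diagonal entries on a fixed ring
#' plus cross-links, giving positive ground-truth partial correlations of
#' moderate size on those edges. Used as the control-group generative model;
#' the patient model scales its off-diagonal entries (see
#' [patient_precision()]).
#'
#' @param n_nodes Number of nodes (default 22).
#' @param coupling Magnitude of the off-diagonal precision entries
#'   (default 0.18); entries are stored as `-coupling`, so planted partial
#'   correlations are approximately `+coupling`.
#' @return A symmetric positive-definite `n_nodes` x `n_nodes` matrix.
#' @export
default_precision <- function(n_nodes = 22, coupling = 0.18) {
  stopifnot(n_nodes >= 2, coupling > 0)
  omega <- diag(n_nodes)
  link <- function(i, j) {
    omega[i, j] <<- -coupling
    omega[j, i] <<- -coupling
  }
  for (i in seq_len(n_nodes - 1L)) link(i, i + 1L)       # ring backbone
  link(1L, n_nodes)
  skip <- seq(1L, n_nodes - 3L, by = 3L)                 # cross-links
  for (i in skip) link(i, i + 3L)
  if (!is_positive_definite(omega)) {
    omega <- nearest_pd(omega)
  }
  omega
}

#' Patient-group precision matrix
#'
#' Scales the off-diagonal entries of a control precision matrix by
#' `coupling_gain` and re-projects to the nearest positive-definite matrix if
#' the scaling breaks positive-definiteness. Larger off-diagonal precision
#' magnitudes yield larger partial correlations, planting a group-level
#' functional-coupling increase with known direction (patients > controls).
#'
#' @param precision Control-group precision matrix (symmetric
#'   positive-definite).
#' @param coupling_gain Multiplier (> 0) applied to off-diagonal entries
#'   (default 1.5).
#' @return A symmetric positive-definite matrix of the same dimension.
#' @export
patient_precision <- function(precision, coupling_gain = 1.5) {
  stopifnot(is.matrix(precision), coupling_gain > 0)
  check_symmetric(precision, "precision")
  omega <- precision * coupling_gain
  diag(omega) <- diag(precision)
  if (!is_positive_definite(omega)) {
    omega <- nearest_pd(omega)
  }
  omega
}

#' Simulate a panel of ROI time series from a planted precision matrix
#'
#' Draws `n_timepoints` observations from a zero-mean multivariate normal
#' whose inverse covariance is `precision`, one column per atlas node. The
#' ground-truth partial correlation matrix implied by the precision is
#' attached so downstream estimators can be validated.
#'
#' @param atlas An `roi_atlas` (defines node count and column names).
#' @param precision Symmetric positive-definite node x node precision matrix.
#' @param n_timepoints Number of timepoints T; must exceed the node count.
#' @param seed Integer seed; identical seeds give identical panels.
#' @return A `timeseries_panel`: a T x N numeric matrix with ROI-name
#'   column names and attributes `node_order` and `truth` (the ground-truth
#'   partial correlation matrix).
#' @examples
#' atlas <- make_roi_atlas()
#' panel <- simulate_timeseries_panel(atlas, default_precision(), 200, seed = 1)
#' dim(panel)
#' @export
simulate_timeseries_panel <- function(atlas, precision, n_timepoints, seed) {
  n <- nrow(atlas)
  stopifnot(is.matrix(precision), nrow(precision) == n, ncol(precision) == n)
  check_symmetric(precision, "precision")
  if (n_timepoints <= n) {
    stop("`n_timepoints` must exceed the number of nodes (", n, ").",
         call. = FALSE)
  }
  ev <- eigen(precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("`precision` must be positive-definite.", call. = FALSE)
  }
  sigma <- chol2inv(chol(precision))
  cs <- chol(sigma)
  withr_seed(seed)
  z <- matrix(stats::rnorm(n_timepoints * n), nrow = n_timepoints, ncol = n)
  x <- z %*% cs
  colnames(x) <- atlas$name
  structure(x,
            node_order = atlas$name,
            truth = precision_to_partial(precision),
            class = c("timeseries_panel", "matrix", "array"))
}

#' Ground-truth partial correlations of a precision matrix
#'
#' Closed form: `r_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj)`, zero diagonal.
#'
#' @param precision Symmetric positive-definite matrix.
#' @return Symmetric matrix of partial correlations with zero diagonal.
#' @export
precision_to_partial <- function(precision) {
  d <- sqrt(diag(precision))
  p <- -precision / tcrossprod(d)
  diag(p) <- 0
  p
}

# Seed handling: every stochastic generator in the package goes through this
# helper so a single integer fully determines its output.
withr_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  set.seed(as.integer(seed))
}

# Deterministic per-subject seed derived from a master seed; kept within
# 32-bit integer range.
derive_seed <- function(master_seed, index) {
  (as.double(master_seed) * 48271 + index * 1299721) %% 2147483647
}

is_positive_definite <- function(m, tol = 1e-10) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol * max(abs(ev))
}

nearest_pd <- function(m) {
  as.matrix(Matrix::nearPD(m, keepDiag = TRUE)$mat)
}

check_symmetric <- function(m, name, tol = 1e-8) {
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) {
    stop("`", name, "` must be symmetric.", call. = FALSE)
  }
  invisible(TRUE)
}
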