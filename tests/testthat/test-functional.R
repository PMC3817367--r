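test_that("sphere extraction averages exactly the voxels inside each ROI", {
  # two disjoint spheres over distinct constant regions
  dims <- c(20L, 12L, 12L, 3L)
  vol <- array(0, dims)
  affine <- diag(4)  # 1 mm voxels at integer mm coordinates
  atlas <- switchnet:::new_roi_atlas(tibble::tibble(
    name = c("a", "b"),
    x_mm = c(4, 14), y_mm = c(5, 5), z_mm = c(5, 5), radius_mm = 3))
  vol[1:10, , , ] <- 7
  vol[11:20, , , ] <- -2
  panel <- extract_roi_timeseries(vol, atlas, affine)
  expect_equal(dim(panel), c(3L, 2L))
  expect_true(all(panel[, "a"] == 7))
  expect_true(all(panel[, "b"] == -2))
})

test_that("a sphere straddling two values averages them voxel-exactly", {
  dims <- c(20L, 12L, 12L, 2L)
  vol <- array(0, dims)
  affine <- diag(4)
  # value depends on x: a left of 8.5, b right of it; center between planes
  vol[1:9, , , ] <- 3
  vol[10:20, , , ] <- 11
  atlas <- switchnet:::new_roi_atlas(tibble::tibble(
    name = "mid", x_mm = 8.5, y_mm = 5, z_mm = 5, radius_mm = 2.4))
  panel <- extract_roi_timeseries(vol, atlas, affine)
  # direct voxel-average oracle
  ijk <- as.matrix(expand.grid(x = 0:19, y = 0:11, z = 0:11))
  inside <- (ijk[, 1] - 8.5)^2 + (ijk[, 2] - 5)^2 + (ijk[, 3] - 5)^2 <= 2.4^2
  vals <- vol[, , , 1][ijk[inside, , drop = FALSE] + 1]
  expect_equal(unname(panel[1, 1]), mean(vals))
  expect_equal(unname(panel[1, 1]), 7)  # equal counts of 3 and 11
})

test_that("empty spheres raise an error naming the ROI", {
  vol <- array(1, c(5L, 5L, 5L, 2L))
  atlas <- switchnet:::new_roi_atlas(tibble::tibble(
    name = "far", x_mm = 100, y_mm = 100, z_mm = 100, radius_mm = 2))
  expect_error(extract_roi_timeseries(vol, atlas, diag(4)), "far")
  expect_error(extract_roi_timeseries(array(1, c(5, 5, 5)), atlas, diag(4)),
               "4-D")
})

test_that("partial correlations match the regression-residual oracle", {
  set.seed(21)
  for (trial in 1:20) {
    n <- sample(3:8, 1)
    x <- matrix(rnorm(200 * n), 200, n)
    # induce some correlation structure
    x <- x %*% matrix(rnorm(n * n, sd = 0.4), n) + x
    p <- partial_correlation_matrix(x)
    expect_equal(unclass_keep_dim(p), oracle_partial_residual(x),
                 tolerance = 1e-8)
  }
})

test_that("partial correlations are symmetric, bounded, zero-diagonal", {
  set.seed(22)
  for (trial in 1:20) {
    n <- sample(3:10, 1)
    x <- matrix(rnorm(150 * n), 150, n)
    p <- partial_correlation_matrix(x)
    expect_equal(max(abs(p - t(p))), 0)
    expect_true(all(diag(p) == 0))
    expect_true(all(abs(p) <= 1 + 1e-12))
  }
})

test_that("degenerate panels are rejected with actionable errors", {
  x <- matrix(rnorm(10 * 22), 10, 22)
  expect_error(partial_correlation_matrix(x), "ridge")
  expect_silent(partial_correlation_matrix(x, ridge = 0.5))
  const <- matrix(rnorm(50 * 3), 50, 3)
  const[, 2] <- 1
  colnames(const) <- c("a", "b", "c")
  expect_error(partial_correlation_matrix(const), "zero variance")
})

test_that("negativity handling follows the selected mode", {
  m <- connectivity_matrix(matrix(c(0, -0.3, -0.3, 0), 2), "functional",
                           "signed", node_order = c("a", "b"))
  zeroed <- weight_functional(m, "zero_negatives")
  expect_equal(unname(unclass_keep_dim(zeroed)), matrix(0, 2, 2))
  absd <- weight_functional(m, "absolute")
  expect_equal(unname(unclass_keep_dim(absd)),
               matrix(c(0, 0.3, 0.3, 0), 2))
  pos <- connectivity_matrix(matrix(c(0, 0.4, 0.4, 0), 2), "functional",
                             "signed")
  expect_equal(unclass_keep_dim(weight_functional(pos, "zero_negatives")),
               unclass_keep_dim(weight_functional(pos, "absolute")))
  expect_error(weight_functional(m, "clip"))
})

test_that("binarization maps strictly non-zero weights to one", {
  w <- connectivity_matrix(matrix(c(0, 2.7, 2.7, 0), 2), "structural",
                           "weighted")
  expect_equal(unname(unclass_keep_dim(binarize(w))),
               matrix(c(0, 1, 1, 0), 2))
  z <- connectivity_matrix(matrix(0, 2, 2), "structural", "weighted")
  expect_equal(sum(binarize(z)), 0)
  tiny <- connectivity_matrix(matrix(c(0, 1e-12, 1e-12, 0), 2),
                              "functional", "weighted")
  expect_equal(binarize(tiny)[1, 2], 1)
  # optional magnitude threshold
  expect_equal(binarize(tiny, threshold = 1e-6)[1, 2], 0)
})

test_that("the planted group coupling effect propagates to edge weights", {
  atlas <- make_roi_atlas()
  omega <- default_precision()
  gain <- patient_precision(omega, 1.5)
  wins <- vapply(1:20, function(s) {
    pat <- simulate_timeseries_panel(atlas, gain, 200, seed = 3000 + s)
    con <- simulate_timeseries_panel(atlas, omega, 200, seed = 6000 + s)
    mw <- function(p) {
      w <- weight_functional(partial_correlation_matrix(p))
      mean(w[upper.tri(w)])
    }
    mw(pat) > mw(con)
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
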