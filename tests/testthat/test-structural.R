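test_that("count_matrix applies the pairwise pass-through rule", {
  atlas <- test_atlas(4)
  centers <- as.matrix(atlas[, c("x_mm", "y_mm", "z_mm")])
  # one polyline passing through spheres 1, 2 and 3
  line <- rbind(centers[1, ], centers[2, ], centers[3, ])
  cm <- count_matrix(make_streamline_set(list(line)), atlas)
  expect_equal(cm[1, 2], 1)
  expect_equal(cm[1, 3], 1)
  expect_equal(cm[2, 3], 1)
  expect_equal(sum(cm), 6)  # three symmetric pairs
  expect_true(all(diag(cm) == 0))
})

test_that("an empty streamline set gives the zero matrix", {
  atlas <- test_atlas(3)
  cm <- count_matrix(make_streamline_set(list()), atlas)
  expect_equal(sum(cm), 0)
  expect_equal(dim(cm), c(3L, 3L))
})

test_that("count_matrix is invariant to streamline direction", {
  cfg <- random_phantom_config(2)
  ph <- simulate_tensor_phantom(cfg$atlas, cfg$bundles, seed = 9)
  sl <- track_streamlines(ph$volume, tracking_params(seed_spacing_mm = 3))
  fwd <- count_matrix(sl, cfg$atlas)
  rev_sl <- make_streamline_set(lapply(sl$coords, function(m) {
    m[rev(seq_len(nrow(m))), , drop = FALSE]
  }))
  expect_equal(unclass_keep_dim(count_matrix(rev_sl, cfg$atlas)),
               unclass_keep_dim(fwd))
})

test_that("FA weighting averages streamline FA per connection", {
  # uniform anisotropic field: every connecting streamline has the field FA
  vol <- uniform_volume(dim = c(61L, 13L, 13L), axis = c(1, 0, 0))
  field_fa <- fa_from_tensor(diag(c(1.7, 0.2, 0.2) * 1e-3))
  atlas <- switchnet:::new_roi_atlas(tibble::tibble(
    name = c("left", "right"),
    x_mm = c(6, 54), y_mm = 6, z_mm = 6, radius_mm = 6))
  sl <- track_streamlines(vol, tracking_params(seed_spacing_mm = 4))
  fw <- fa_weight_matrix(sl, vol, atlas)
  cm <- count_matrix(sl, atlas)
  expect_gt(cm[1, 2], 0)
  expect_equal(fw[1, 2], field_fa, tolerance = 1e-6)
  # no-connection entries stay zero
  expect_equal(fa_weight_matrix(make_streamline_set(list()), vol, atlas)[1, 2],
               0)
})

test_that("fa_weight_matrix averages over connecting streamlines", {
  # two hand-made streamlines through both spheres; volume FA is uniform so
  # the mean-of-means equals the field FA; with a manual mixed set the
  # entry is the mean of per-streamline means
  vol <- uniform_volume(dim = c(31L, 9L, 9L), axis = c(1, 0, 0))
  atlas <- switchnet:::new_roi_atlas(tibble::tibble(
    name = c("a", "b"), x_mm = c(4, 26), y_mm = 4, z_mm = 4, radius_mm = 4))
  l1 <- cbind(seq(2, 28, by = 1), 4, 4)
  l2 <- cbind(seq(2, 28, by = 1), 5, 5)
  fw <- fa_weight_matrix(make_streamline_set(list(l1, l2)), vol, atlas)
  mean_fa <- mean(c(mean(fa_at_points(vol, l1)), mean(fa_at_points(vol, l2))))
  expect_equal(fw[1, 2], mean_fa, tolerance = 1e-12)
})

test_that("phantom tractography recovers the planted adjacency", {
  set.seed(51)
  for (trial in 1:5) {
    cfg <- random_phantom_config()
    ph <- simulate_tensor_phantom(cfg$atlas, cfg$bundles, seed = 70 + trial)
    sl <- track_streamlines(ph$volume, tracking_params())
    cm <- count_matrix(sl, cfg$atlas)
    expect_equal(unclass_keep_dim(binarize(cm)), cfg$adjacency)
  }
})

test_that("normalization modes behave as documented", {
  m <- connectivity_matrix(matrix(c(0, 3, 1, 3, 0, 0, 1, 0, 0), 3),
                           "structural", "weighted")
  raw <- normalize_structural(m, "raw")
  expect_equal(unclass_keep_dim(raw), unclass_keep_dim(m))
  frac <- normalize_structural(m, "total_fraction")
  expect_equal(frac[1, 2], 0.75)
  expect_equal(frac[1, 3], 0.25)
  expect_equal(sum(frac[upper.tri(frac)]), 1)
  z <- connectivity_matrix(matrix(0, 2, 2), "structural", "weighted")
  expect_error(normalize_structural(z, "total_fraction"), "zero")
  single <- connectivity_matrix(matrix(c(0, 3, 3, 0), 2), "structural",
                                "weighted")
  expect_equal(normalize_structural(single, "total_fraction")[1, 2], 1)
})
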