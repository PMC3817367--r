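star5 <- function() {
  m <- matrix(0, 5, 5)
  m[1, 2:5] <- m[2:5, 1] <- 1
  connectivity_matrix(m, "functional", "binary")
}

test_that("degree and strength follow their definitions on canonical graphs", {
  s <- star5()
  expect_equal(unname(nodal_degree(s)), c(4, 1, 1, 1, 1))
  z <- connectivity_matrix(matrix(0, 4, 4), "functional", "binary")
  expect_equal(unname(nodal_degree(z)), rep(0, 4))
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.2
  w[1, 3] <- w[3, 1] <- 0.3
  wm <- connectivity_matrix(w, "functional", "weighted")
  expect_equal(unname(nodal_strength(wm)), c(0.5, 0.2, 0.3))
  # degree of a weighted matrix equals degree of its binarized matrix
  expect_equal(nodal_degree(wm), nodal_degree(binarize(wm)))
  # binary strength equals degree
  expect_equal(nodal_strength(s), nodal_degree(s))
})

test_that("strength equals an independent summation over edges", {
  set.seed(61)
  for (trial in 1:10) {
    n <- sample(4:9, 1)
    m <- random_graph(n)
    sums <- vapply(seq_len(n), function(i) sum(m[i, ]), numeric(1))
    expect_equal(unname(nodal_strength(as_cm_test(m))), sums)
  }
})

test_that("shortest paths use 1/weight lengths", {
  # binary path a-b-c
  p <- matrix(0, 3, 3)
  p[1, 2] <- p[2, 1] <- 1
  p[2, 3] <- p[3, 2] <- 1
  d <- shortest_path_lengths(connectivity_matrix(p, "functional", "binary"))
  expect_equal(d[1, 3], 2)
  # weighted edge 0.5 has length 2
  w <- matrix(0, 2, 2)
  w[1, 2] <- w[2, 1] <- 0.5
  dw <- shortest_path_lengths(connectivity_matrix(w, "functional",
                                                  "weighted"))
  expect_equal(dw[1, 2], 2)
  # disconnected pairs are infinite
  dz <- shortest_path_lengths(connectivity_matrix(matrix(0, 2, 2),
                                                  "functional", "binary"))
  expect_equal(dz[1, 2], Inf)
})

test_that("local efficiency and betweenness behave on canonical graphs", {
  k3 <- connectivity_matrix(1 - diag(3), "functional", "binary")
  expect_equal(unname(local_efficiency(k3)), rep(1, 3))
  s <- star5()
  expect_equal(unname(local_efficiency(s)), rep(0, 5))
  # path a-b-c: b mediates the single shortest path
  p <- matrix(0, 3, 3)
  p[1, 2] <- p[2, 1] <- 1
  p[2, 3] <- p[3, 2] <- 1
  bc <- betweenness_centrality(connectivity_matrix(p, "functional",
                                                   "binary"))
  expect_equal(unname(bc), c(0, 1, 0))
  # complete graphs have zero betweenness everywhere
  k5 <- connectivity_matrix(1 - diag(5), "functional", "binary")
  expect_equal(unname(betweenness_centrality(k5)), rep(0, 5))
  expect_equal(global_efficiency(k5), 1)
})

test_that("graph metrics match exhaustive path enumeration", {
  set.seed(62)
  for (trial in 1:25) {
    n <- sample(4:8, 1)
    weighted <- trial %% 2 == 0
    m <- random_graph(n, p_edge = 0.45, weighted = weighted)
    cm <- as_cm_test(m)
    oracle <- oracle_paths(m)
    expect_equal(unname(shortest_path_lengths(cm)), oracle$dist,
                 tolerance = 1e-9)
    expect_equal(unname(betweenness_centrality(cm)), oracle$betweenness,
                 tolerance = 1e-9)
    expect_equal(unname(local_efficiency(cm)), oracle_local_efficiency(m),
                 tolerance = 1e-9)
  }
})

test_that("leaf nodes always have zero betweenness", {
  set.seed(63)
  for (trial in 1:10) {
    m <- random_graph(sample(5:8, 1), p_edge = 0.35)
    bc <- betweenness_centrality(as_cm_test(m))
    leaves <- which(rowSums(m > 0) == 1)
    if (length(leaves) > 0) expect_true(all(bc[leaves] == 0))
  }
})

test_that("metrics are equivariant under node relabeling", {
  set.seed(64)
  m <- random_graph(7)
  cm <- as_cm_test(m)
  perm <- sample(7)
  mp <- m[perm, perm]
  cmp <- as_cm_test(mp)
  expect_equal(unname(nodal_degree(cmp)), unname(nodal_degree(cm))[perm])
  expect_equal(unname(nodal_strength(cmp)), unname(nodal_strength(cm))[perm])
  expect_equal(unname(betweenness_centrality(cmp)),
               unname(betweenness_centrality(cm))[perm], tolerance = 1e-10)
  expect_equal(unname(local_efficiency(cmp)),
               unname(local_efficiency(cm))[perm], tolerance = 1e-10)
})

test_that("network_summary is the mean over nodes", {
  expect_equal(network_summary(rep(3.3, 22)), 3.3)
  expect_equal(network_summary(c(0, 1)), 0.5)
  set.seed(65)
  v <- runif(22)
  expect_equal(network_summary(v), sum(v) / 22)
  expect_error(network_summary(numeric(0)), "Empty")
})

test_that("the 2-SD hub rule flags exactly the outlying nodes", {
  # equal node means: no hubs (strict inequality at SD 0)
  flat <- matrix(5, 4, 6)
  colnames(flat) <- paste0("n", 1:6)
  expect_equal(sum(identify_hubs(flat)$is_hub), 0)
  # one node far above the rest
  b <- matrix(1, 5, 8)
  b[, 3] <- 50
  colnames(b) <- paste0("n", 1:8)
  rep <- identify_hubs(b)
  expect_identical(rep$node[rep$is_hub], "n3")
  # random matrix: matches a direct reapplication of the rule
  set.seed(66)
  r <- matrix(rexp(10 * 22), 10, 22)
  colnames(r) <- paste0("n", 1:22)
  rep2 <- identify_hubs(r)
  means <- colMeans(r)
  thr <- mean(means) + 2 * sd(means)
  expect_equal(rep2$is_hub, unname(means > thr))
  expect_equal(attr(rep2, "threshold"), thr)
  expect_error(identify_hubs(r[1, , drop = FALSE]), "two subjects")
  expect_error(identify_hubs(r[, 1, drop = FALSE]), "two nodes")
})

test_that("nodal_metrics returns one tidy row per node", {
  set.seed(67)
  cm <- as_cm_test(random_graph(6))
  nm <- nodal_metrics(cm)
  expect_equal(nrow(nm), 6)
  expect_named(nm, c("node", "degree", "strength", "local_efficiency",
                     "betweenness"))
  expect_equal(nm$degree, unname(nodal_degree(cm)))
})
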