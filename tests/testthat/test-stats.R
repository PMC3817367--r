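test_that("two-sample t matches hand computation and the oracle", {
  res <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674234614174767, tolerance = 1e-10)
  expect_equal(res$df, 4)
  same <- two_sample_t(c(2, 4, 6), c(2, 4, 6))
  expect_equal(same$t, 0)
  set.seed(71)
  for (trial in 1:50) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), mean = 0.5)
    pooled <- two_sample_t(a, b, "pooled")
    o <- oracle_t(a, b, pooled = TRUE)
    expect_equal(pooled$t, unname(o["t"]), tolerance = 1e-10)
    expect_equal(pooled$p, unname(o["p"]), tolerance = 1e-10)
    welch <- two_sample_t(a, b, "welch")
    ow <- oracle_t(a, b, pooled = FALSE)
    expect_equal(welch$t, unname(ow["t"]), tolerance = 1e-10)
    expect_equal(welch$df, unname(ow["df"]), tolerance = 1e-10)
  }
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
  expect_error(two_sample_t(c(1, 1, 1), c(2, 2, 2)), "constant")
})

test_that("pearson_r matches hand computation and the oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_equal(pearson_r(x, c(2, 1, 4, 3))$r, 0.6, tolerance = 1e-12)
  set.seed(72)
  for (trial in 1:50) {
    n <- sample(4:30, 1)
    a <- rnorm(n); b <- rnorm(n) + 0.3 * a
    res <- pearson_r(a, b)
    o <- oracle_pearson(a, b)
    expect_equal(res$r, unname(o["r"]), tolerance = 1e-10)
    expect_equal(res$p, unname(o["p"]), tolerance = 1e-10)
  }
  expect_error(pearson_r(c(1, 2), c(3, 4)), "3 pairs")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("switch cost is the correct-trial switch minus repeat mean", {
  tbl <- tibble::tibble(
    block = "switch",
    trial_index = 1:4,
    cue = "global",
    trial_type = c("switch", "switch", "repeat", "repeat"),
    rt_ms = c(670, 682, 640, 642),
    correct = TRUE)
  expect_equal(switch_cost(tbl), 676 - 641)
  # incorrect trials are excluded
  tbl$correct[2] <- FALSE
  expect_equal(switch_cost(tbl), 670 - 641)
  no_switch_block <- dplyr::mutate(tbl, block = "pure_global")
  expect_error(switch_cost(no_switch_block), "both types")
  # identical distributions: near-zero cost in expectation
  cfg <- cohort_config()
  cfg$rt_params$mean_ms[cfg$rt_params$condition %in%
                          c("switch", "repeat")] <- 600
  set.seed(73)
  costs <- vapply(1:200, function(s) {
    switch_cost(simulate_behavior("control", cfg, seed = 5000 + s))
  }, numeric(1))
  expect_lt(abs(mean(costs)), 10)
})

test_that("mixed ANOVA matches an explicit sums-of-squares oracle", {
  set.seed(74)
  for (trial in 1:10) {
    n <- 8  # per group, balanced for the closed-form oracle
    d <- tidyr::expand_grid(subject = sprintf("s%02d", 1:(2 * n)),
                            condition = c("c1", "c2"))
    d$group <- ifelse(as.integer(substring(d$subject, 2)) <= n, "g1", "g2")
    d$value <- rnorm(nrow(d)) +
      ifelse(d$group == "g1" & d$condition == "c1", trial / 10, 0)
    res <- mixed_anova_2x2(d)
    o <- oracle_mixed_anova_balanced(d$value, d$subject, d$group,
                                     d$condition)
    expect_equal(res$F[res$effect == "group"], o$F_group, tolerance = 1e-8)
    expect_equal(res$F[res$effect == "condition"], o$F_cond,
                 tolerance = 1e-8)
    expect_equal(res$F[res$effect == "group:condition"], o$F_int,
                 tolerance = 1e-8)
    expect_equal(res$df1, rep(1, 3))
    expect_equal(res$df2, rep(2 * n - 2, 3))
  }
})

test_that("ANOVA interaction responds to a planted interaction", {
  make_data <- function(effect, seed) {
    set.seed(seed)
    n <- 16
    d <- tidyr::expand_grid(subject = sprintf("s%02d", 1:(2 * n)),
                            condition = c("repeat", "switch"))
    d$group <- ifelse(as.integer(substring(d$subject, 2)) <= n,
                      "patient", "control")
    d$value <- rnorm(nrow(d), sd = 1) +
      ifelse(d$group == "patient" & d$condition == "switch", effect, 0)
    d
  }
  # equal group-mean condition differences: interaction SS is exactly zero
  # (small integers, so the cell means cancel without rounding error)
  flat <- tibble::tibble(
    subject = rep(c("s1", "s2", "s3", "s4"), each = 2),
    group = rep(c("g1", "g1", "g2", "g2"), each = 2),
    condition = rep(c("c1", "c2"), 4),
    value = c(0, 1, 0, 3, 5, 6, 5, 8))
  res0 <- mixed_anova_2x2(flat)
  expect_equal(res0$F[res0$effect == "group:condition"], 0)
  # interaction F grows with the planted effect, averaged over noise draws
  int_f <- function(effect) {
    mean(vapply(1:10, function(s) {
      r <- mixed_anova_2x2(make_data(effect, 10 + s))
      r$F[r$effect == "group:condition"]
    }, numeric(1)))
  }
  expect_gt(int_f(3), int_f(0.3))
  rejections <- vapply(1:10, function(s) {
    r <- mixed_anova_2x2(make_data(3, 10 + s))
    r$p[r$effect == "group:condition"] < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.8)
  expect_error(mixed_anova_2x2(make_data(1, 3)[-1, ]), "exactly one value")
})

test_that("cross-modal association handles identical and mismatched input", {
  set.seed(75)
  metrics <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:12),
                                node = paste0("n", 1:5))
  metrics$group <- ifelse(as.integer(substring(metrics$subject_id, 2)) <= 6,
                          "patient", "control")
  for (m in c("degree", "strength", "local_efficiency", "betweenness")) {
    metrics[[m]] <- runif(nrow(metrics))
  }
  res <- crossmodal_association(metrics, metrics, "global")
  expect_equal(res$r, rep(1, 8), tolerance = 1e-12)
  expect_equal(nrow(res), 8)  # 4 metrics x 2 groups
  nodal <- crossmodal_association(metrics, metrics, "nodal")
  expect_equal(nrow(nodal), 5)  # one row per node
  expect_equal(nodal$r, rep(1, 5), tolerance = 1e-12)
  other <- dplyr::mutate(metrics, subject_id = paste0("x", subject_id))
  expect_error(crossmodal_association(metrics, other, "global"),
               "same subjects")
})

test_that("independent metrics rarely show strong global correlations", {
  set.seed(76)
  hits <- 0
  reps <- 300
  for (trial in seq_len(reps)) {
    a <- rnorm(16); b <- rnorm(16)
    hits <- hits + (abs(pearson_r(a, b)$r) >= 0.6)
  }
  expect_lt(hits / reps, 0.05)
})
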