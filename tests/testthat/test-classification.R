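test_that("median split labels strictly-above-median subjects as good", {
  expect_equal(median_split(c(1, 2, 3, 4)), c(0L, 0L, 1L, 1L))
  expect_equal(median_split(c(1, 2, 2, 3)), c(0L, 0L, 0L, 1L))
  expect_equal(median_split(c(1, 2, 3, 4, 5)), c(0L, 0L, 0L, 1L, 1L))
  expect_error(median_split(rep(2, 6)), "degenerate")
  expect_error(median_split(c(1, 2)), "4 subjects")
})

test_that("a perfectly separating feature yields perfect classification", {
  x <- matrix(c(1, 2, 3, 11, 12, 13), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  rep <- lda_classify(x, y)
  expect_equal(rep$overall, 100)
  expect_equal(rep$sensitivity, 100)
  expect_equal(rep$specificity, 100)
  expect_lt(rep$wilks_lambda, 0.1)
  # two subjects per class, separable
  rep2 <- lda_classify(matrix(c(0, 1, 10, 11), ncol = 1), c(0, 0, 1, 1))
  expect_equal(rep2$overall, 100)
})

test_that("confusion counts are consistent with the reported percentages", {
  set.seed(81)
  for (trial in 1:10) {
    n <- sample(10:30, 1)
    x <- matrix(rnorm(n * 2), n, 2)
    y <- rep(c(0L, 1L), length.out = n)
    rep <- lda_classify(x, y)
    expect_equal(rep$sensitivity, 100 * rep$tp / (rep$tp + rep$fn))
    expect_equal(rep$specificity, 100 * rep$tn / (rep$tn + rep$fp))
    expect_equal(rep$overall, 100 * (rep$tp + rep$tn) / n)
    expect_gte(rep$wilks_lambda, 0)
    expect_lte(rep$wilks_lambda, 1)
  }
})

test_that("single-feature Wilks' lambda obeys the t-statistic identity", {
  set.seed(82)
  for (trial in 1:100) {
    n1 <- sample(4:15, 1); n2 <- sample(4:15, 1)
    x <- matrix(c(rnorm(n1), rnorm(n2, mean = runif(1, 0, 2))), ncol = 1)
    y <- c(rep(0L, n1), rep(1L, n2))
    rep <- lda_classify(x, y)
    t_stat <- two_sample_t(x[y == 0L], x[y == 1L])$t
    n <- n1 + n2
    expect_equal(rep$wilks_lambda, 1 / (1 + t_stat^2 / (n - 2)),
                 tolerance = 1e-10)
  }
})

test_that("wilks lambda weakly decreases with planted separation", {
  set.seed(83)
  effects <- c(0, 0.5, 1, 2, 4)
  mean_wilks <- vapply(effects, function(e) {
    mean(vapply(1:20, function(s) {
      x <- matrix(c(rnorm(12), rnorm(12, mean = e)), ncol = 1)
      lda_classify(x, rep(c(0L, 1L), each = 12))$wilks_lambda
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_wilks) < 0))
})

test_that("resubstitution predictions agree with an independent LDA", {
  set.seed(84)
  for (trial in 1:20) {
    n <- sample(12:30, 1)
    x <- matrix(rnorm(n * 2), n, 2)
    y <- rep(c(0L, 1L), length.out = n)
    x[y == 1L, 1] <- x[y == 1L, 1] + runif(1, 0, 2)
    rep <- lda_classify(x, y)
    fit <- MASS::lda(x, grouping = factor(y))
    pred <- as.integer(as.character(stats::predict(fit, x)$class))
    expect_equal(100 * mean(pred == y), rep$overall)
  }
})

test_that("permuted labels give chance-level out-of-sample accuracy", {
  set.seed(85)
  n <- 24
  x <- matrix(rnorm(n), ncol = 1)
  acc_loo <- vapply(1:200, function(s) {
    y <- sample(rep(c(0L, 1L), each = n / 2))
    lda_classify_loo(x, y)$overall
  }, numeric(1))
  # chance for balanced classes is 50%; binomial SE over 200 * 24 trials
  expect_lt(abs(mean(acc_loo) - 50), 7.5)
  acc_resub <- vapply(1:100, function(s) {
    y <- sample(rep(c(0L, 1L), each = n / 2))
    lda_classify(x, y)$overall
  }, numeric(1))
  # resubstitution can only look better than chance on average
  expect_gte(mean(acc_resub), 50)
})

test_that("the model suite runs all three feature sets", {
  set.seed(86)
  n <- 20
  score <- runif(n)
  degrees <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:n),
    structural_degree = rnorm(n),
    functional_degree = score + rnorm(n, sd = 0.3))
  scores <- tibble::tibble(subject_id = degrees$subject_id, score = score)
  suite <- run_model_suite(degrees, scores)
  expect_equal(suite$model, c("structural", "functional", "combined"))
  expect_true(all(suite$wilks_lambda >= 0 & suite$wilks_lambda <= 1))
  # identical feature columns: combined equals the single-modality reports
  same <- dplyr::mutate(degrees, structural_degree = functional_degree)
  suite2 <- run_model_suite(same, scores)
  expect_equal(suite2$overall[suite2$model == "combined"],
               suite2$overall[suite2$model == "functional"])
  bad <- dplyr::mutate(scores, subject_id = paste0("x", subject_id))
  expect_error(run_model_suite(degrees, bad), "same subjects")
})

test_that("the modality carrying the planted signal classifies better", {
  set.seed(87)
  diffs <- vapply(1:15, function(s) {
    n <- 24
    score <- runif(n)
    degrees <- tibble::tibble(
      subject_id = sprintf("s%02d", 1:n),
      structural_degree = rnorm(n),                      # noise only
      functional_degree = score + rnorm(n, sd = 0.2))    # carries signal
    scores <- tibble::tibble(subject_id = degrees$subject_id, score = score)
    suite <- run_model_suite(degrees, scores)
    suite$overall[suite$model == "functional"] -
      suite$overall[suite$model == "structural"]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("tidiers return well-formed tibbles", {
  x <- matrix(c(1, 2, 3, 11, 12, 13), ncol = 1)
  rep <- lda_classify(x, c(0, 0, 0, 1, 1, 1), model = "demo")
  td <- generics::tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "classification_report"))
  gl <- generics::glance(rep)
  expect_equal(gl$best_model, "demo")
})
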