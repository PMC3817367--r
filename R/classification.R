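# Median-split discriminant analyses: do structural, functional, or combined
# connectivity-degree features predict good vs poor switching performance?
# Classification uses a two-class linear discriminant with resubstitution;
# discriminatory power is summarized by Wilks' lambda = det(W)/det(T)
# (within- vs total-scatter), 1 = no discrimination, 0 = perfect.

#' Median split of a performance score
#'
#' Label 1 ("good") for scores strictly above the sample median; scores at or
#' below the median (including ties at the median) go to the lower class.
#'
#' @param scores Numeric vector, length >= 4, not all equal.
#' @return Integer vector of 0/1 labels.
#' @export
median_split <- function(scores) {
  if (length(scores) < 4L) stop("At least 4 subjects are required.",
                                call. = FALSE)
  if (length(unique(scores)) == 1L) {
    stop("All scores are equal; the median split is degenerate.",
         call. = FALSE)
  }
  as.integer(scores > stats::median(scores))
}

#' Linear discriminant classification report
#'
#' Fits a two-class linear discriminant (equal-covariance Gaussian rule with
#' proportional priors) on the feature matrix, classifies the training
#' subjects themselves (resubstitution), and reports the confusion counts,
#' sensitivity (true good / all good, with "good" = label 1 as positives),
#' specificity (true poor / all poor), overall accuracy, and Wilks' lambda
#' from the within- and total-scatter matrices. A small ridge is added to a
#' singular pooled covariance.
#'
#' @param features Subject x feature numeric matrix (or data frame).
#' @param labels Binary 0/1 vector, >= 2 subjects per class.
#' @param ridge Relative ridge added to the pooled within-class covariance
#'   when it is numerically singular (default 1e-8).
#' @param model Optional label stored in the report (e.g. `"functional"`).
#' @return A `classification_report` (one-row tibble): `model`, confusion
#'   counts (`tp`, `fn`, `tn`, `fp`), `sensitivity`, `specificity`,
#'   `overall`, percentages, and `wilks_lambda`.
#' @export
lda_classify <- function(features, labels, ridge = 1e-8, model = "model") {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  y <- as.integer(labels)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)))
  if (min(table(y)) < 2L) {
    stop("At least 2 subjects per class are required.", call. = FALSE)
  }
  n <- nrow(x); p <- ncol(x)
  m0 <- colMeans(x[y == 0L, , drop = FALSE])
  m1 <- colMeans(x[y == 1L, , drop = FALSE])
  grand <- colMeans(x)
  w <- crossprod(sweep(x[y == 0L, , drop = FALSE], 2, m0)) +
       crossprod(sweep(x[y == 1L, , drop = FALSE], 2, m1))
  tot <- crossprod(sweep(x, 2, grand))
  wilks <- det(w) / det(tot)

  sp <- w / (n - 2)
  sp_inv <- tryCatch(solve(sp), error = function(e) {
    scale <- mean(diag(sp))
    if (!is.finite(scale) || scale <= 0) scale <- 1
    solve(sp + ridge * scale * diag(p))
  })
  prior1 <- mean(y); prior0 <- 1 - prior1
  score <- function(m, prior) {
    drop(x %*% sp_inv %*% m) - 0.5 * drop(m %*% sp_inv %*% m) + log(prior)
  }
  pred <- as.integer(score(m1, prior1) > score(m0, prior0))

  tp <- sum(pred == 1L & y == 1L)
  fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  fp <- sum(pred == 1L & y == 0L)
  out <- tibble::tibble(
    model = model,
    tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    overall = 100 * (tp + tn) / n,
    wilks_lambda = wilks
  )
  class(out) <- c("classification_report", class(out))
  out
}

#' Leave-one-out variant of the discriminant report
#'
#' Extension of [lda_classify()]: each subject is classified by a model
#' fitted on the remaining subjects. Wilks' lambda is still computed on the
#' full sample.
#'
#' @inheritParams lda_classify
#' @return A `classification_report` tibble.
#' @export
lda_classify_loo <- function(features, labels, ridge = 1e-8,
                             model = "model_loo") {
  x <- as.matrix(features)
  y <- as.integer(labels)
  n <- nrow(x)
  pred <- integer(n)
  for (i in seq_len(n)) {
    fit <- lda_predict(x[-i, , drop = FALSE], y[-i], x[i, , drop = FALSE],
                       ridge)
    pred[i] <- fit
  }
  tp <- sum(pred == 1L & y == 1L)
  fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  fp <- sum(pred == 1L & y == 0L)
  full <- lda_classify(x, y, ridge, model)
  out <- dplyr::mutate(full, tp = tp, fn = fn, tn = tn, fp = fp,
                       sensitivity = 100 * tp / (tp + fn),
                       specificity = 100 * tn / (tn + fp),
                       overall = 100 * (tp + tn) / n,
                       model = model)
  class(out) <- c("classification_report", class(out))
  out
}

lda_predict <- function(x, y, newx, ridge) {
  p <- ncol(x)
  m0 <- colMeans(x[y == 0L, , drop = FALSE])
  m1 <- colMeans(x[y == 1L, , drop = FALSE])
  w <- crossprod(sweep(x[y == 0L, , drop = FALSE], 2, m0)) +
       crossprod(sweep(x[y == 1L, , drop = FALSE], 2, m1))
  sp <- w / (nrow(x) - 2)
  sp_inv <- tryCatch(solve(sp), error = function(e) {
    scale <- mean(diag(sp))
    if (!is.finite(scale) || scale <= 0) scale <- 1
    solve(sp + ridge * scale * diag(p))
  })
  prior1 <- mean(y); prior0 <- 1 - prior1
  s1 <- drop(newx %*% sp_inv %*% m1) - 0.5 * drop(m1 %*% sp_inv %*% m1) +
    log(prior1)
  s0 <- drop(newx %*% sp_inv %*% m0) - 0.5 * drop(m0 %*% sp_inv %*% m0) +
    log(prior0)
  as.integer(s1 > s0)
}

#' Run the three discriminant models
#'
#' Structural-only, functional-only, and combined (both features jointly)
#' discriminant analyses of good vs poor switching performance. Features are
#' per-subject network-summary connectivity degrees; labels come from a
#' median split of the behavioral scores.
#'
#' @param cohort_degrees Tibble with columns `subject_id`,
#'   `structural_degree`, `functional_degree`.
#' @param behavior_scores Tibble with columns `subject_id`, `score`
#'   (switch-block accuracy), same subjects.
#' @return A `classification_report` tibble with one row per model.
#' @export
run_model_suite <- function(cohort_degrees, behavior_scores) {
  joined <- dplyr::inner_join(cohort_degrees, behavior_scores,
                              by = "subject_id")
  if (nrow(joined) != nrow(cohort_degrees) ||
      nrow(joined) != nrow(behavior_scores)) {
    stop("Degree and score tables must cover the same subjects.",
         call. = FALSE)
  }
  labels <- median_split(joined$score)
  reports <- dplyr::bind_rows(
    lda_classify(joined["structural_degree"], labels, model = "structural"),
    lda_classify(joined["functional_degree"], labels, model = "functional"),
    lda_classify(joined[c("structural_degree", "functional_degree")], labels,
                 model = "combined")
  )
  class(reports) <- c("classification_report", class(reports))
  reports
}
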