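# broom-style tidiers for the package's result objects. Most statistics in
# the package already return tidy tibbles; these methods cover the classed
# report objects.

#' Tidy a classification report
#'
#' @param x A `classification_report`.
#' @param ... Unused.
#' @return One row per model: confusion counts, sensitivity/specificity/
#'   overall percentages, Wilks' lambda.
#' @export
tidy.classification_report <- function(x, ...) {
  tibble::as_tibble(unclass_report(x))
}

#' Summarize a classification report
#'
#' @param x A `classification_report`.
#' @param ... Unused.
#' @return One row: best model by overall accuracy, its accuracy, and the
#'   range of Wilks' lambda across models.
#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x),
    best_model = x$model[which.max(x$overall)],
    best_overall = max(x$overall),
    min_wilks = min(x$wilks_lambda),
    max_wilks = max(x$wilks_lambda)
  )
}

#' Tidy a hub report
#'
#' @param x A `hub_report`.
#' @param ... Unused.
#' @return One row per node with the hub flag and the threshold attached as
#'   a column.
#' @export
tidy.hub_report <- function(x, ...) {
  out <- tibble::as_tibble(unclass_report(x))
  out$threshold <- attr(x, "threshold")
  out
}

unclass_report <- function(x) {
  class(x) <- setdiff(class(x), c("classification_report", "hub_report"))
  x
}
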