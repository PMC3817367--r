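# ggplot2 views of the main result types.

#' Heatmap of a connectivity matrix
#'
#' @param object A `connectivity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  df <- tibble::as_tibble(unclass_matrix(object), rownames = "from")
  df <- tidyr::pivot_longer(df, -"from", names_to = "to",
                            values_to = "weight")
  order <- attr(object, "node_order")
  df$from <- factor(df$from, levels = rev(order))
  df$to <- factor(df$to, levels = order)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      title = paste(matrix_modality(object), matrix_weighting(object),
                    "connectivity"),
      x = NULL, y = NULL, fill = "weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Group distributions of per-subject network summaries
#'
#' One panel per metric: each point is a subject's mean-over-nodes value,
#' jittered within group, with a boxplot underneath.
#'
#' @param metrics Long metric tibble from [cohort_metrics()].
#' @return A ggplot object.
#' @export
plot_metric_distributions <- function(metrics) {
  metric_names <- c("degree", "strength", "local_efficiency", "betweenness")
  summaries <- dplyr::summarise(
    dplyr::group_by(metrics, .data$subject_id, .data$group),
    dplyr::across(dplyr::all_of(metric_names), mean), .groups = "drop")
  long <- tidyr::pivot_longer(summaries, dplyr::all_of(metric_names),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "network summary (mean over nodes)") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' Hub profile plot
#'
#' Mean nodal betweenness across subjects with the mean + 2 SD hub threshold.
#'
#' @param object A `hub_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hub_report <- function(object, ...) {
  thr <- attr(object, "threshold")
  df <- dplyr::mutate(object, node = factor(.data$node,
                                            levels = .data$node))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node,
                                   y = .data$mean_betweenness,
                                   fill = .data$is_hub)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "mean betweenness centrality",
                  fill = "hub") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
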