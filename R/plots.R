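#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot retained PCA scores by experimental group
#'
#' Scatter of the first two retained components (or a jittered strip when a
#' single component is retained), coloured by group.
#'
#' @param object A `pca_fit`.
#' @param data The trait table the PCA was fitted on (for group labels).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pca_fit <- function(object, data = NULL, ...) {
  sc <- augment(object, data)
  cols <- paste0(".", object$component_names)
  has_group <- !is.null(data) && "group" %in% names(data)
  if (length(cols) >= 2) {
    p <- ggplot2::ggplot(sc, ggplot2::aes(
      x = .data[[cols[1]]], y = .data[[cols[2]]],
      colour = if (has_group) .data$group else NULL)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::labs(x = object$component_names[1],
                    y = object$component_names[2], colour = "group")
  } else {
    p <- ggplot2::ggplot(sc, ggplot2::aes(
      x = if (has_group) .data$group else factor(1),
      y = .data[[cols[1]]])) +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.8) +
      ggplot2::labs(x = NULL, y = object$component_names[1])
  }
  p + ggplot2::theme_minimal()
}

#' Plot an overlap report grid
#'
#' Bar panel of overlap and hybrid-contribution percentages per engine and
#' trait set.
#'
#' @param object An `overlap_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.overlap_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$grid, "trait_set", "engine", "overlap",
                  "hybrid_contribution"),
    cols = c("overlap", "hybrid_contribution"),
    names_to = "quantity", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$engine, y = .data$percent,
                                     fill = .data$trait_set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~quantity) +
    ggplot2::labs(x = NULL, y = "percent", fill = "trait set") +
    ggplot2::theme_minimal()
}

#' Violin plot of one trait across the five groups
#'
#' @param data A trait table.
#' @param variable Unquoted trait column.
#' @return A ggplot object.
#' @export
plot_trait_by_group <- function(data, variable) {
  data <- assign_groups(data)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$group,
                                     y = {{ variable }},
                                     fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.12, fill = "white", outlier.size = 0.6,
                          show.legend = FALSE) +
    ggplot2::theme_minimal()
}
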