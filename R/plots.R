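#' Plot per-slice metric values
#'
#' Sharpness-across-the-stack line plot: slice index on the x axis (top of
#' the spheroid at 1), metric value on the y axis, one line per stack.
#'
#' @param plots metric-plot tibble from [evaluate_stack()].
#' @param colour column (tidy-eval) mapped to line colour; default
#'   `stack_id`.
#' @return A ggplot object.
#' @export
plot_metric_values <- function(plots, colour = NULL) {
  colour <- rlang::enquo(colour)
  if (rlang::quo_is_null(colour)) colour <- rlang::quo(.data$stack_id)
  ggplot2::ggplot(plots,
                  ggplot2::aes(x = .data$slice, y = .data$value,
                               colour = !!colour,
                               group = .data$stack_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "slice (top to bottom)", y = "metric value",
                  title = unique(plots$metric)[1],
                  subtitle = paste("masking:",
                                   paste(unique(plots$masking), collapse = ", "))) +
    ggplot2::theme_minimal()
}

#' @method autoplot sqm_scoreset
#' @export
autoplot.sqm_scoreset <- function(object, ...) {
  has_region <- "region" %in% names(object)
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$stack_id, y = .data$score01)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "score (0-1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (has_region) p <- p + ggplot2::facet_wrap(~region)
  p
}

#' @method autoplot sqm_correlation
#' @export
autoplot.sqm_correlation <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$metric_score, y = .data$expert_score,
                               colour = .data$region)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                         formula = y ~ x, se = FALSE, colour = "grey40") +
    ggplot2::labs(x = paste("metric score (", object$score_col, ")"),
                  y = "expert score (1-5)") +
    ggplot2::theme_minimal()
}

#' @method autoplot sqm_group_comparison
#' @export
autoplot.sqm_group_comparison <- function(object, ...) {
  d <- object$dunn
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group1, y = .data$group2,
                                  fill = -log10(.data$p_adjusted))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars)) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = "-log10 adj. p") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Dunn pairwise comparisons") +
    ggplot2::theme_minimal()
}
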