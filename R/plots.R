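#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ISC time course
#'
#' One line per expression channel: mean pairwise correlation per sliding
#' window against window start time.
#'
#' @param object An [sliding_window_isc()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot isc_timecourse
#' @export
autoplot.isc_timecourse <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$window_start_s, y = .data$mean_r,
                               colour = .data$expression)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "window start (s)", y = "mean pairwise r",
                  colour = "expression",
                  title = "Sliding-window inter-subject correlation") +
    ggplot2::theme_minimal()
}

#' Heatmap of a cross-expression correlation matrix
#'
#' @param object A [between_expression_matrix()] or
#'   [individual_vs_rest_matrix()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cross_expression_matrix
#' @export
autoplot.cross_expression_matrix <- function(object, ...) {
  df <- tidy.cross_expression_matrix(object)
  ylab <- if (identical(attr(object, "type"), "individual_vs_rest")) {
    "individual"
  } else "expression"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expression_col,
                                   y = .data$expression_row,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$r), "", sprintf("%.2f", .data$r))),
      size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1),
                                  na.value = "grey85") +
    ggplot2::scale_y_discrete(limits = rev(.channels())) +
    ggplot2::labs(x = "rest of audience", y = ylab, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Scatterplot of pair synchrony against seat proximity
#'
#' Fisher-z pair ISC against the square root of seat distance, with a
#' least-squares line, facetted by expression.
#'
#' @param table A [pairwise_isc()] table.
#' @param expressions Channels to show (default all eight).
#' @return A ggplot.
#' @export
plot_proximity <- function(table, expressions = expression_channels()) {
  stopifnot(inherits(table, "pair_isc_table"))
  df <- tibble::as_tibble(table)
  df <- df[df$expression %in% expressions & !is.na(df$z), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = sqrt(.data$seat_distance),
                                   y = .data$z)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#b2182b", linewidth = 0.6) +
    ggplot2::facet_wrap(~expression, scales = "free_y") +
    ggplot2::labs(x = "sqrt(seat distance)", y = "pair ISC (Fisher z)") +
    ggplot2::theme_minimal()
}

#' Plot an engagement course over the ISC window grid
#'
#' @param object A [resample_engagement()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot engagement_course
#' @export
autoplot.engagement_course <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$window_start_s,
                               y = .data$engagement)) +
    ggplot2::geom_line(colour = "#e08214") +
    ggplot2::scale_y_continuous(limits = c(1, 3)) +
    ggplot2::labs(x = "window start (s)",
                  y = "predicted engagement (1-3)") +
    ggplot2::theme_minimal()
}

#' Group-mean plot of pair synchrony by gender and age groups
#'
#' @param contrast A [group_contrast()] result.
#' @return A ggplot.
#' @export
plot_group_means <- function(contrast) {
  stopifnot(inherits(contrast, "group_contrast"))
  ggplot2::ggplot(contrast$cell_means,
                  ggplot2::aes(x = .data$gender_group, y = .data$mean_z,
                               fill = .data$age_group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "gender group", y = "mean pair ISC (Fisher z)",
                  fill = "age group") +
    ggplot2::theme_minimal()
}
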