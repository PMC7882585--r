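#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_boxplot geom_col
#'   geom_segment geom_hline facet_wrap labs theme_minimal arrow unit
NULL

#' Plot a diversity partition
#'
#' Per-site standardised beta deviation (or any partition column) by group,
#' as jittered points over a boxplot, with the null expectation at zero.
#'
#' @param object A [diversity_partition()] result.
#' @param column Which column to display (default `"beta_dev"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diversity_partition <- function(object, column = "beta_dev", ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$group, y = .data[[column]])) +
    geom_boxplot(outlier.shape = NA, fill = "grey92") +
    geom_point(position = ggplot2::position_jitter(width = 0.15, seed = 1),
               alpha = 0.7) +
    (if (column == "beta_dev") geom_hline(yintercept = 0, linetype = 2)) +
    labs(x = "group", y = column) +
    theme_minimal()
}

#' Plot a constrained ordination
#'
#' Site scores on the first two constrained axes, coloured by group when
#' available, with predictor biplot arrows.
#'
#' @param object A [cap_fit()] result.
#' @param arrow_scale Multiplier applied to the biplot arrows.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cap_fit <- function(object, arrow_scale = NULL, ...) {
  sc <- as.data.frame(object$site_scores)
  if (ncol(sc) < 2) abort("Fewer than two constrained axes to plot.")
  sc$group <- object$group %||% "all"
  bp <- as.data.frame(object$biplot_scores)
  bp$term <- rownames(bp)
  arrow_scale <- arrow_scale %||% (0.8 * max(abs(sc[, 1:2])))
  ggplot(sc, aes(x = .data$CAP1, y = .data$CAP2)) +
    geom_point(aes(colour = .data$group)) +
    geom_segment(data = bp,
                 aes(x = 0, y = 0, xend = arrow_scale * .data$CAP1,
                     yend = arrow_scale * .data$CAP2),
                 arrow = arrow(length = unit(2, "mm")), colour = "grey30") +
    ggplot2::geom_text(data = bp,
                       aes(x = 1.08 * arrow_scale * .data$CAP1,
                           y = 1.08 * arrow_scale * .data$CAP2,
                           label = .data$term),
                       size = 3, colour = "grey30") +
    labs(x = "CAP axis 1", y = "CAP axis 2") +
    theme_minimal()
}

#' Plot varimax-rotated loadings
#'
#' Bar panels of the rotated loadings, one facet per retained axis.
#'
#' @param object A [pca_varimax()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_varimax <- function(object, ...) {
  df <- tidy.pca_varimax(object)
  ggplot(df, aes(x = .data$loading, y = .data$variable)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~ .data$axis) +
    labs(x = "rotated loading", y = NULL) +
    theme_minimal()
}

#' Plot a variable screening table
#'
#' Signed z values of the two-group Mann-Whitney comparisons, ordered by
#' magnitude, significant variables (table-wise FDR) highlighted.
#'
#' @param object A [screen_variables()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screening_table <- function(object, ...) {
  df <- as_tibble(object)
  df$variable <- stats::reorder(df$variable, abs(df$z))
  ggplot(df, aes(x = .data$z, y = .data$variable, fill = .data$significant)) +
    geom_col() +
    labs(x = "Mann-Whitney z", y = NULL, fill = "q < 0.05") +
    theme_minimal()
}
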