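#' Stacked composition profile across distance bins
#'
#' @param profile Tibble from [bin_composition()].
#' @return A ggplot object: stacked cell-type proportions per distance bin.
#' @export
plot_composition <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                               y = .data$prop, fill = .data$label)) +
    ggplot2::geom_col(width = abs(profile$bin_hi[1] - profile$bin_lo[1])) +
    ggplot2::labs(x = "signed distance (px)", y = "proportion",
                  fill = "cell type") +
    ggplot2::theme_minimal()
}

#' Boxplot of |d_vessel| by endothelial state
#'
#' @param x A `state_distance_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.state_distance_profile <- function(x, ...) {
  ggplot2::ggplot(x$data, ggplot2::aes(x = .data$state, y = .data$abs_d)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::labs(x = NULL, y = "|distance to vessel wall| (px)") +
    ggplot2::theme_minimal()
}

#' Coefficient plot of the selected invasion genes
#'
#' @param x An `invasion_model`.
#' @param ... Unused.
#' @return A ggplot object: selected genes ordered by coefficient.
#' @export
autoplot.invasion_model <- function(x, ...) {
  df <- dplyr::arrange(x$selected, .data$beta)
  df$gene <- factor(df$gene, levels = df$gene)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$gene,
                                   fill = .data$sign)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "coefficient (depth px per SD)", y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' iScore against decidual depth
#'
#' @param scores Tibble from [score_cells()].
#' @param depths Tibble with `cell_id`, `depth_px`.
#' @return A ggplot object with a smoothing line.
#' @export
plot_iscore_depth <- function(scores, depths) {
  df <- dplyr::inner_join(scores, depths, by = "cell_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_px, y = .data$iscore)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "decidual depth (px)", y = "iScore (section-normalized)") +
    ggplot2::theme_minimal()
}

#' Boxplot of iScores by stromal-adjacency group
#'
#' @param x An `adjacency_contrast`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adjacency_contrast <- function(x, ...) {
  ggplot2::ggplot(x$data, ggplot2::aes(x = .data$group, y = .data$iscore)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::labs(x = NULL, y = "iScore") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
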