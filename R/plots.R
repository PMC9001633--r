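# ggplot2 graphics: cell-map helper and autoplot methods for result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tile map of a per-cell metric
#'
#' @param data A tibble with `lon`, `lat` and the metric column (e.g. from
#'   [cell_richness()], [cell_pd()], [phylogenetic_endemism()]).
#' @param metric Unquoted metric column to fill by.
#' @return A ggplot object.
#' @export
plot_cell_map <- function(data, metric) {
  ggplot2::ggplot(data, ggplot2::aes(.data$lon, .data$lat,
                                     fill = {{ metric }})) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
}

#' @rdname canape_classify
#' @param object A `canape_result`.
#' @param ... Unused.
#' @export
autoplot.canape_result <- function(object, ...) {
  cols <- c(not_significant = "grey80", neo = "#d7191c", paleo = "#2c7bb6",
            mixed = "#b58fc2", super = "#5e3c99")
  ggplot2::ggplot(object, ggplot2::aes(.data$lon, .data$lat,
                                       fill = .data$endemism_type)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = cols, name = "Endemism") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
}

#' @rdname dtt
#' @param object A `dtt_result`.
#' @param ... Unused.
#' @export
autoplot.dtt_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$rel_time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80", alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_median),
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), linewidth = 0.8) +
    ggplot2::labs(x = "Relative time", y = "Mean relative disparity") +
    ggplot2::theme_minimal()
}

#' @rdname niche_pca
#' @param object A `niche_pca`.
#' @param axes Pair of axis numbers to display.
#' @param ... Unused.
#' @export
autoplot.niche_pca <- function(object, axes = c(1, 2), ...) {
  sc <- object$scores
  xa <- paste0("PC", axes[1])
  ya <- paste0("PC", axes[2])
  ggplot2::ggplot(sc, ggplot2::aes(.data[[xa]], .data[[ya]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xa, object$percent_variance[axes[1]]),
      y = sprintf("%s (%.1f%%)", ya, object$percent_variance[axes[2]])) +
    ggplot2::theme_minimal()
}

#' Plot traitgram segments
#'
#' @param segments Output of [traitgram()].
#' @return A ggplot object.
#' @export
plot_traitgram <- function(segments) {
  ggplot2::ggplot(segments) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$time_parent,
                                       y = .data$value_parent,
                                       xend = .data$time_child,
                                       yend = .data$value_child),
                          alpha = 0.7) +
    ggplot2::labs(x = "Time (Myr from root)", y = "Trait value") +
    ggplot2::theme_minimal()
}

#' Plot a lineage-through-time curve
#'
#' @param ltt Output of [ltt_curve()], or a list of such tibbles (e.g.
#'   over a posterior tree set), drawn as overlaid step curves.
#' @return A ggplot object.
#' @export
plot_ltt <- function(ltt) {
  if (is.data.frame(ltt)) ltt <- list(ltt)
  df <- purrr::imap_dfr(ltt, ~dplyr::mutate(.x, tree = .y))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$lineages,
                                   group = .data$tree)) +
    ggplot2::geom_step(alpha = max(0.1, 1 / length(ltt))) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (Myr from root)", y = "Lineages") +
    ggplot2::theme_minimal()
}
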