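# ggplot2 figure layer. Every plot_*()/autoplot() returns a ggplot object
# the caller can restyle.

#' LC-diagram scatter of complexity profiles
#'
#' Plots profiled segments in the complexity triangle — mutation percentage
#' on x, dominance percentage on y — coloured by segment class, with the
#' 50/50 operational cuts and the x + y = 100 triangle edge drawn in.
#'
#' @param profiles Output of [profile_regions()] or rows of
#'   [profile_segment()].
#' @return A ggplot.
#' @export
plot_lc_diagram <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$mutation_pct, y = .data$dominance_pct,
                               colour = .data$segment_class)) +
    ggplot2::annotate("segment", x = 0, y = 100, xend = 100, yend = 0,
                      linetype = "dotted", colour = "grey50") +
    ggplot2::geom_vline(xintercept = 50, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_fixed(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(x = "Mutation to perfect repeat (%)",
                  y = "Most frequent amino acid (%)",
                  colour = "Segment") +
    ggplot2::theme_minimal()
}

#' Heatmap of a Jaccard similarity matrix
#'
#' @param m A matrix from [jaccard_matrix()].
#' @return A ggplot.
#' @export
plot_jaccard_heatmap <- function(m) {
  df <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(df) <- c("method_a", "method_b", "jaccard")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method_a, y = .data$method_b,
                                   fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$jaccard)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Purity-retention curves per method
#'
#' @param retention Output of [purity_retention()].
#' @return A ggplot.
#' @export
plot_retention <- function(retention) {
  ggplot2::ggplot(retention,
                  ggplot2::aes(x = .data$threshold, y = .data$retained,
                               colour = .data$method)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Purity threshold (%)", y = "Fraction retained",
                  colour = "Method") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Per-tier purity and entropy trends
#'
#' @param tiers Output of [tier_summaries()].
#' @return A ggplot.
#' @export
plot_tier_summaries <- function(tiers) {
  long <- tiers |>
    dplyr::select("k", "entropy_median", "purity_median") |>
    tidyr::pivot_longer(-"k", names_to = "metric", values_to = "median")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$median)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Consensus level k", y = "Median") +
    ggplot2::theme_minimal()
}

#' Stratified TPR/FPR line plot
#'
#' @param metrics The `strata` tibble of [evaluate_stratified()].
#' @return A ggplot.
#' @export
plot_stratified_metrics <- function(metrics) {
  long <- metrics |>
    dplyr::select("method", "stratum", "tpr", "fpr") |>
    tidyr::pivot_longer(c("tpr", "fpr"), names_to = "rate",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stratum, y = .data$value,
                                     colour = .data$method,
                                     group = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~rate, ncol = 2) +
    ggplot2::labs(x = "Stratum", y = "Rate", colour = "Method") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a binned LC-space surface
#'
#' @param object An `lcr_surface`.
#' @param ... Unused.
#' @return A ggplot heat map of P(LC | x, y).
#' @export
autoplot.lcr_surface <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$x, y = .data$y,
                                            fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0.5,
                                  limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Mutation to perfect repeat (%)",
                  y = "Most frequent amino acid (%)", fill = "P(LC)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.lcr_surface
#' @export
autoplot.lcr_smooth <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$x, y = .data$y,
                                            fill = .data$prob)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0.5,
                                  limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Mutation to perfect repeat (%)",
                  y = "Most frequent amino acid (%)", fill = "P(LC)") +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object An `lcr_roc`.
#' @param ... Unused.
#' @return A ggplot with the Youden-optimal operating point marked.
#' @export
autoplot.lcr_roc <- function(object, ...) {
  star <- object$curve[object$curve$threshold == object$t_star, ]
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = star, colour = "firebrick", size = 2) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate") +
    ggplot2::theme_minimal()
}

#' Plot an estimated LC boundary
#'
#' Probability surface with the P(LC) = t* contour overlaid.
#'
#' @param object An `lcr_boundary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lcr_boundary <- function(object, ...) {
  p <- autoplot(object$surface)
  if (nrow(object$contour) > 0L) {
    p <- p + ggplot2::geom_path(
      data = object$contour,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$piece),
      inherit.aes = FALSE, linewidth = 0.8)
  }
  p
}
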