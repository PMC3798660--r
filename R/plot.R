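# ggplot2 views of networks, orientation statistics and ensembles.

# Line-segment table (x1, y1, x2, y2, kind) for a network, optionally at a
# deformed state.
segment_table <- function(network, state = NULL) {
  xs <- if (is.null(state)) network$nodes$x else state$coordinates[, 1]
  ys <- if (is.null(state)) network$nodes$y else state$coordinates[, 2]
  beams <- tibble::tibble(
    x1 = xs[network$beams$node_a], y1 = ys[network$beams$node_a],
    x2 = xs[network$beams$node_b], y2 = ys[network$beams$node_b],
    kind = "beam")
  cables <- if (NROW(network$cables)) tibble::tibble(
    x1 = xs[network$cables$node_a], y1 = ys[network$cables$node_a],
    x2 = xs[network$cables$node_b], y2 = ys[network$cables$node_b],
    kind = "cable") else NULL
  dplyr::bind_rows(beams, cables)
}

#' Plot a filament network
#'
#' Filaments are drawn as solid green segments and cross-linkers as dashed
#' blue segments, at the reference geometry or at a deformed state.
#'
#' @param object A `filament_network`.
#' @param state Optional `system_state` giving deformed coordinates.
#' @param cables Draw the cross-linkers as well (default TRUE; dense
#'   networks are easier to read without them).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.filament_network <- function(object, state = NULL, cables = TRUE,
                                      ...) {
  seg <- segment_table(object, state)
  if (!cables) seg <- dplyr::filter(seg, .data$kind == "beam")
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x1, y = .data$y1,
                   xend = .data$x2, yend = .data$y2,
                   colour = .data$kind, linetype = .data$kind),
      linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(beam = "darkgreen", cable = "steelblue")) +
    ggplot2::scale_linetype_manual(
      values = c(beam = "solid", cable = "dashed")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = NULL,
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the form-found configuration next to the generated one
#'
#' @param object A `form_finding_result`.
#' @param ... Passed to [autoplot.filament_network()].
#' @return A ggplot of the form-found geometry.
#' @export
autoplot.form_finding_result <- function(object, ...) {
  autoplot(object$network, state = object$state, ...) +
    ggplot2::ggtitle("form-found configuration")
}

#' Histogram plot of folded segment orientations
#'
#' @param network A `filament_network`.
#' @param state Optional deformed `system_state`.
#' @param breaks Bin edges in degrees.
#' @return A ggplot.
#' @export
plot_orientation_histogram <- function(network, state = NULL,
                                       breaks = seq(0, 90, by = 10)) {
  h <- orientation_histogram(network, state, breaks)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_left + .data$bin_right) / 2,
                                  y = .data$fraction)) +
    ggplot2::geom_col(width = diff(breaks)[1] * 0.9, fill = "darkgreen") +
    ggplot2::labs(x = "segment angle to stretch axis (deg)",
                  y = "fraction of segments") +
    ggplot2::theme_minimal()
}

#' Histogram plot of ensemble moduli
#'
#' @param object An `ensemble_result`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot, faceted by sweep value when sweeping.
#' @export
autoplot.ensemble_result <- function(object, bins = 20, ...) {
  p <- ggplot2::ggplot(object$samples,
                       ggplot2::aes(x = .data$modulus)) +
    ggplot2::geom_histogram(bins = bins, fill = "darkgreen",
                            colour = "white") +
    ggplot2::labs(x = "effective modulus (kPa)", y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(object$spec$sweep_variable))
    p <- p + ggplot2::facet_wrap(~sweep_value)
  p
}

#' Mean-modulus trend across a sweep
#'
#' Plots the per-sweep-point mean with +/- one standard deviation bars.
#'
#' @param result An `ensemble_result` from a sweep.
#' @return A ggplot.
#' @export
plot_sweep_trend <- function(result) {
  s <- result$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$sweep_value, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = result$spec$sweep_variable %||% "sweep value",
                  y = "mean effective modulus (kPa)") +
    ggplot2::theme_minimal()
}
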