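#' Binarized activity raster
#'
#' Units on the y axis, time on the x axis; active frames drawn dark.
#'
#' @param mask An `activity_mask`.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @return The mask, invisibly.
#' @export
plot_raster <- function(mask, main = "activity raster", ...) {
  stopifnot(inherits(mask, "activity_mask"))
  t_s <- (seq_len(n_frames(mask)) - 1L) / mask$fps
  graphics::image(t_s, seq_len(n_units(mask)), t(mask$active),
                  col = c("white", "grey20"), xlab = "time (s)",
                  ylab = "unit", main = main, useRaster = TRUE, ...)
  invisible(mask)
}

#' Correlation map over the neuron layout
#'
#' Draws unit centroids at their pixel positions and connects pairs whose
#' coefficient exceeds `threshold`; positive connections red, negative
#' blue, line width scaled by |r|.
#'
#' @param corr A `correlation_matrix`.
#' @param pos A [neuron_positions()] table for the same units.
#' @param threshold Minimum |r| for an edge to be drawn.
#' @param main Plot title.
#' @return Invisible data frame of the drawn edges.
#' @export
plot_correlation_map <- function(corr, pos, threshold = 0.3,
                                 main = "correlation map") {
  stopifnot(inherits(pos, "neuron_positions"))
  n <- nrow(corr)
  graphics::plot(pos$x, pos$y, pch = 19, cex = 0.8, col = "grey40",
                 xlab = "x (px)", ylab = "y (px)", main = main, asp = 1)
  idx <- which(upper.tri(corr) & abs(corr) > threshold, arr.ind = TRUE)
  if (nrow(idx)) {
    r <- corr[idx]
    graphics::segments(pos$x[idx[, 1]], pos$y[idx[, 1]],
                       pos$x[idx[, 2]], pos$y[idx[, 2]],
                       col = ifelse(r > 0, "#d62728", "#1f77b4"),
                       lwd = 0.5 + 2 * abs(r))
  }
  invisible(data.frame(i = idx[, 1], j = idx[, 2], r = corr[idx]))
}

#' Network degree curve plot
#'
#' @param x A [network_degree()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.network_degree <- function(x, ...) {
  graphics::plot(x$threshold, x$percent, type = "b", pch = 19,
                 xlab = "correlation threshold",
                 ylab = "% connected pairs", ...)
  invisible(x)
}
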