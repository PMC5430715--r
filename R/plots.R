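# Base-graphics plots mirroring the standard displays of the analysis.

TYPE_COLORS <- c(intra_object = "#d62728", trans_object = "#1f77b4",
                 object_to_background = "#ff9896",
                 background_to_object = "#aec7e8",
                 background_to_background = "#7f7f7f")

#' Plot saccade-type ratio curves by saccade order
#'
#' One line per saccade type; optionally overlays a second set of curves
#' (e.g. model expectation over empirical ratios, dashed).
#'
#' @param r A `ratio_curves` matrix.
#' @param overlay Optional second `ratio_curves` drawn dashed.
#' @param expected_switch Optional saccade order marked by a vertical line
#'   (e.g. `1 / p_sw`).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `r`.
#' @export
plot_ratio_curves <- function(r, overlay = NULL, expected_switch = NULL,
                              ...) {
  graphics::matplot(seq_len(nrow(r)), unclass(r), type = "l", lty = 1,
                    lwd = 2, col = TYPE_COLORS, xlab = "saccade order",
                    ylab = "type ratio", ylim = c(0, 1), ...)
  if (!is.null(overlay)) {
    graphics::matlines(seq_len(nrow(overlay)), unclass(overlay), lty = 2,
                       lwd = 1.5, col = TYPE_COLORS)
  }
  if (!is.null(expected_switch)) {
    graphics::abline(v = expected_switch, col = "magenta", lty = 3)
  }
  graphics::legend("topright", legend = colnames(r), col = TYPE_COLORS,
                   lty = 1, lwd = 2, cex = 0.7, bty = "n")
  invisible(r)
}

#' Plot the GoF profile over the switch probability
#'
#' @param fit A `fit_result` from [grid_search_fit()] (switch model).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the profile data.frame.
#' @export
plot_gof_profile <- function(fit, ...) {
  pr <- fit$gof_profile
  if (is.null(pr)) stop("no p_sw profile in a no-switch fit")
  graphics::plot(pr$p_sw, pr$gof, type = "b", pch = 16,
                 xlab = expression(p[SW]), ylab = "max GoF", ...)
  graphics::abline(v = fit$best_params$p_sw, lty = 2)
  invisible(pr)
}

#' Image plot of a GoF plane over a stay-probability pair
#'
#' @param plane A matrix from a `fit_result` (`gof_plane_early` or
#'   `gof_plane_late`).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `plane`.
#' @export
plot_gof_plane <- function(plane, ...) {
  g <- as.numeric(rownames(plane))
  finite <- plane
  finite[!is.finite(finite)] <- max(finite[is.finite(finite)]) * 1.05
  graphics::image(g, as.numeric(colnames(plane)), finite,
                  xlab = "stay probability (intra)",
                  ylab = "stay probability (trans)",
                  col = grDevices::hcl.colors(64L, "viridis"), ...)
  invisible(plane)
}

#' Plot a gaze trace with detected events
#'
#' Horizontal and vertical position over time with saccade periods shaded.
#'
#' @param trace A [gaze_trace()].
#' @param saccades Optional saccade table ([detect_saccades()] output).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `trace`.
#' @export
plot_gaze_trace <- function(trace, saccades = NULL, ...) {
  graphics::plot(trace$t, trace$x, type = "l", col = "black",
                 xlab = "time (s)", ylab = "gaze position (deg)",
                 ylim = range(c(trace$x, trace$y)), ...)
  graphics::lines(trace$t, trace$y, col = "gray50")
  if (!is.null(saccades) && nrow(saccades)) {
    usr <- graphics::par("usr")
    graphics::rect(saccades$onset, usr[3L], saccades$offset, usr[4L],
                   col = grDevices::adjustcolor("gray", 0.4), border = NA)
  }
  graphics::abline(v = attr(trace, "stimulus_onset"), col = "red", lty = 3)
  invisible(trace)
}
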