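#' Plot a fitted Hofstee standard
#'
#' Draws the classic Hofstee chart: the cumulative percentage polyline,
#' the compromise line AB, dashed guide lines at the four parameters, and
#' the cut-off marker with its 2 dp label. \code{mode = "full"} spans the
#' whole data range; \code{mode = "detailed"} zooms to
#' \code{[c_min - m, c_max + m]} with margin \code{m} equal to 10\% of
#' \code{c_max - c_min}, the region where the compromise is decided.
#'
#' @param x A fitted \code{"hofstee"} object.
#' @param mode \code{"full"} (default) or \code{"detailed"}.
#' @param main Optional title.
#' @param ... Further arguments passed to \code{plot()}.
#' @return \code{x}, invisibly.
#' @export
plot.hofstee <- function(x, mode = c("full", "detailed"), main = NULL, ...) {
  mode <- match.arg(mode)
  draw_hofstee_chart(x$curve, x$line, x$cutoff, mode = mode, main = main, ...)
  invisible(x)
}

draw_hofstee_chart <- function(curve, ab, cutoff = NULL,
                               mode = c("full", "detailed"),
                               main = NULL, ...) {
  mode <- match.arg(mode)
  c_min <- min(ab[c("x1", "x2")]); c_max <- max(ab[c("x1", "x2")])
  f_min <- min(ab[c("y1", "y2")]); f_max <- max(ab[c("y1", "y2")])
  if (mode == "detailed") {
    m <- 0.1 * (c_max - c_min)
    xlim <- c(c_min - m, c_max + m)
    inwin <- curve$x >= xlim[1L] & curve$x <= xlim[2L]
    ywin <- c(curve$y[inwin], f_min, f_max,
              if (!is.null(cutoff) && !isTRUE(cutoff$fallback)) cutoff$cutoff_y)
    ylim <- if (length(ywin)) range(ywin) else c(0, 100)
    ylim <- ylim + c(-1, 1) * 0.05 * max(diff(ylim), 1)
  } else {
    xlim <- range(c(curve$x, c_min, c_max))
    ylim <- c(0, 100)
  }
  graphics::plot(NA, xlim = xlim, ylim = ylim,
                 xlab = "Score (%)", ylab = "Cumulative % of students",
                 main = if (is.null(main)) sprintf("Hofstee chart (%s)", mode)
                        else main, ...)
  graphics::abline(v = c(c_min, c_max), lty = 3, col = "grey50")
  graphics::abline(h = c(f_min, f_max), lty = 3, col = "grey50")
  graphics::lines(curve$x, curve$y, lwd = 2, col = "steelblue")
  graphics::segments(ab[["x1"]], ab[["y1"]], ab[["x2"]], ab[["y2"]],
                     lwd = 2, col = "firebrick")
  if (!is.null(cutoff) && !isTRUE(cutoff$fallback)) {
    graphics::points(cutoff$cutoff_x, cutoff$cutoff_y, pch = 19, cex = 1.3)
    graphics::text(cutoff$cutoff_x, cutoff$cutoff_y,
                   sprintf("%.2f", cutoff$display_cutoff),
                   pos = 4, offset = 0.6)
  } else {
    graphics::mtext("no intersection between AB and the cumulative curve",
                    side = 3, line = 0.2, cex = 0.8, col = "firebrick")
  }
  invisible(NULL)
}

#' Render a Hofstee chart to an image file
#'
#' File-writing wrapper around the chart used by [plot.hofstee()];
#' rendering is a pure sink and never changes numeric results.
#'
#' @param curve A \code{cumulative_curve}.
#' @param ab The compromise line ([hofstee_line()]).
#' @param cutoff Optional \code{cutoff_result}; when absent the chart is
#'   still rendered with a diagnostic annotation instead of a marker.
#' @param path Output file path.
#' @param mode \code{"full"} or \code{"detailed"}.
#' @param format \code{"png"} or \code{"svg"}; default inferred from the
#'   file extension, falling back to png.
#' @param width,height Image size in pixels (png) or inches (svg).
#' @param main Optional title.
#' @return \code{path}, invisibly.
#' @export
render_chart <- function(curve, ab, cutoff = NULL, path,
                         mode = c("full", "detailed"), format = NULL,
                         width = NULL, height = NULL, main = NULL) {
  mode <- match.arg(mode)
  if (nrow(curve) == 0L) stop("empty curve", call. = FALSE)
  if (is.null(format))
    format <- if (grepl("\\.svg$", path, ignore.case = TRUE)) "svg" else "png"
  format <- match.arg(format, c("png", "svg"))
  if (format == "png") {
    grDevices::png(path, width = width %||% 1200, height = height %||% 900,
                   res = 150, type = if (capabilities("cairo")) "cairo")
  } else {
    grDevices::svg(path, width = width %||% 8, height = height %||% 6)
  }
  on.exit(grDevices::dev.off())
  draw_hofstee_chart(curve, ab, cutoff, mode = mode, main = main)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
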