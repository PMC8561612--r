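#' Report the largest score gaps near the cut-off
#'
#' A data gap is an interval between adjacent distinct observed scores
#' containing no student. Wide gaps near the cut-off matter when defending
#' a standard: a cut-off placed inside a wide gap separates the same
#' students as any other point in that gap, so examiners may prefer to
#' nudge it to a defensible position. The report is advisory only; the
#' cut-off is never adjusted automatically.
#'
#' @param s A [score_set()].
#' @param window_low,window_high Score interval searched; only gaps whose
#'   both endpoints lie inside it are reported. The natural window is
#'   \code{[c_min, c_max]}, the range the detailed chart covers.
#' @param top_k Number of gaps reported (widest first; ties broken by
#'   lower score ascending). Default 3.
#' @return An object of class \code{"gap_report"}: a data frame with
#'   columns \code{lower}, \code{upper}, \code{width}, sorted by width
#'   descending, plus a \code{window} attribute. Fewer than two distinct
#'   scores in the window yield an empty (zero-row) report.
#' @examples
#' find_gaps(score_set(c(50, 53, 60, 61)), 45, 65, top_k = 1)  # gap 53-60
#' @export
find_gaps <- function(s, window_low, window_high, top_k = 3L) {
  if (!inherits(s, "score_set")) s <- score_set(s)
  if (window_low >= window_high)
    stop("window_low must be less than window_high", call. = FALSE)
  v <- unique(as.numeric(s))
  v <- v[v >= window_low & v <= window_high]
  if (length(v) < 2L) {
    g <- data.frame(lower = numeric(0), upper = numeric(0),
                    width = numeric(0))
  } else {
    g <- data.frame(lower = v[-length(v)], upper = v[-1L])
    g$width <- g$upper - g$lower
    g <- g[order(-g$width, g$lower), , drop = FALSE]
    g <- utils::head(g, top_k)
    rownames(g) <- NULL
  }
  structure(g, window = c(window_low, window_high),
            class = c("gap_report", "data.frame"))
}

#' @export
print.gap_report <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("Largest score gaps in [%g, %g]:\n", w[1L], w[2L]))
  if (nrow(x) == 0L) {
    cat("  (fewer than two distinct scores in window - no gaps)\n")
  } else {
    for (i in seq_len(nrow(x)))
      cat(sprintf("  %g - %g  (width %g)\n",
                  x$lower[i], x$upper[i], x$width[i]))
  }
  invisible(x)
}
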