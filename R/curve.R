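#' Build the cumulative percentage curve of a score set
#'
#' One vertex per distinct score value v at \code{(v, 100 * k / n)}, where
#' k is the number of students scoring at or below v; consecutive vertices
#' are joined by straight segments for all downstream geometry. This
#' rank-based "at or below" convention is load-bearing for the whole
#' method: the cut-off is defined as the intersection of the compromise
#' line with exactly this polyline. No origin vertex is prepended — the
#' curve starts at the minimum observed score, so an intersection below
#' that score cannot exist and is reported as a no-intersection
#' diagnostic downstream. The final vertex always has y = 100.
#'
#' @param s A [score_set()] (or numeric vector, coerced via [score_set()]).
#' @return An object of class \code{"cumulative_curve"}: a data frame with
#'   columns \code{x} (distinct scores, ascending) and \code{y} (cumulative
#'   percent), plus attribute \code{n_students}.
#' @examples
#' build_cumulative_curve(score_set(c(1, 2, 3, 4)))
#' build_cumulative_curve(score_set(c(10, 10, 20)))
#' @export
build_cumulative_curve <- function(s) {
  if (!inherits(s, "score_set")) s <- score_set(s)
  n <- attr(s, "n")
  v <- unique(as.numeric(s))                 # already sorted ascending
  k <- cumsum(tabulate(match(as.numeric(s), v), nbins = length(v)))
  structure(data.frame(x = v, y = 100 * k / n),
            n_students = n,
            class = c("cumulative_curve", "data.frame"))
}

#' @export
print.cumulative_curve <- function(x, ...) {
  cat(sprintf("Cumulative percentage curve: %d vertices, %d students, x in [%g, %g]\n",
              nrow(x), attr(x, "n_students"), x$x[1L], x$x[nrow(x)]))
  invisible(x)
}

#' Evaluate the cumulative curve at a score
#'
#' Linear interpolation along the plotted polyline; exactly the vertex y
#' at a vertex x. Defined only on the curve's x-range (the polyline does
#' not extend beyond the observed scores).
#'
#' @param c A \code{cumulative_curve}.
#' @param x Score(s) at which to evaluate; must lie within
#'   \code{[min(c$x), max(c$x)]}.
#' @return Cumulative percent value(s) at \code{x}.
#' @examples
#' cv <- build_cumulative_curve(score_set(c(1, 2, 3, 4)))
#' curve_value_at(cv, 2.5)   # 62.5
#' @export
curve_value_at <- function(c, x) {
  rng <- range(c$x)
  if (any(x < rng[1L] | x > rng[2L]))
    stop(sprintf("score %g outside the curve's x-range [%g, %g]",
                 x[which(x < rng[1L] | x > rng[2L])][1L], rng[1L], rng[2L]),
         call. = FALSE)
  if (nrow(c) == 1L) return(rep(c$y, length(x)))
  stats::approx(c$x, c$y, xout = x, method = "linear", ties = "ordered")$y
}

#' Export the curve vertices as a two-column CSV for audit
#'
#' @param c A \code{cumulative_curve}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_curve <- function(c, path) {
  utils::write.csv(data.frame(score = c$x, cumulative_percent = c$y),
                   path, row.names = FALSE)
  invisible(path)
}
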