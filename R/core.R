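#' Line segments in (score, percent) coordinates
#'
#' @param x1,y1,x2,y2 Endpoint coordinates.
#' @return An object of class \code{"line_segment"}: a named numeric
#'   vector \code{x1, y1, x2, y2}.
#' @export
line_segment <- function(x1, y1, x2, y2) {
  v <- c(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
    stop("segment endpoints must be finite numbers", call. = FALSE)
  if (x1 == x2 && y1 == y2)
    stop("degenerate segment: endpoints coincide", call. = FALSE)
  structure(as.numeric(v), names = names(v), class = "line_segment")
}

#' @export
print.line_segment <- function(x, ...) {
  cat(sprintf("Segment (%g, %g)-(%g, %g)\n",
              x[["x1"]], x[["y1"]], x[["x2"]], x[["y2"]]))
  invisible(x)
}

#' Construct the compromise line AB from Hofstee parameters
#'
#' A is the point (c_min, f_max) — the lowest acceptable standard paired
#' with the highest acceptable failure rate — and B is (c_max, f_min).
#' Every point on AB trades a higher standard against a lower failure
#' rate; its crossing with the cumulative curve is the compromise cut-off.
#' AB is vertical when \code{c_min == c_max} and horizontal when
#' \code{f_min == f_max}; it degenerates to a point (an error) only when
#' both hold.
#'
#' @param p A [hofstee_params()] object, or a numeric vector
#'   \code{c(c_min, c_max, f_min, f_max)}.
#' @return A [line_segment()] from A to B.
#' @examples
#' hofstee_line(hofstee_params(35, 45, 6, 18))   # (35,18)-(45,6)
#' @export
hofstee_line <- function(p) {
  if (!inherits(p, "hofstee_params"))
    p <- hofstee_params(p[[1L]], p[[2L]], p[[3L]], p[[4L]])
  if (p[["c_min"]] == p[["c_max"]] && p[["f_min"]] == p[["f_max"]])
    stop("degenerate parameters: line AB is a point", call. = FALSE)
  line_segment(p[["c_min"]], p[["f_max"]], p[["c_max"]], p[["f_min"]])
}

#' Intersect two closed line segments
#'
#' Returns the unique point lying on both closed segments, or \code{NULL}
#' when the segments are disjoint, parallel and non-collinear, or
#' collinear without overlap. For collinear overlapping segments the point
#' of smallest x in the overlap is returned (smallest y when both are
#' vertical) — for a horizontal compromise line lying along a flat curve
#' stretch this picks the lowest passing standard consistent with the
#' judgement. Endpoint membership is tested with an absolute tolerance of
#' \code{tol} (default 1e-9), so crossings that coincide with a shared
#' vertex are accepted from either adjacent segment.
#'
#' @param a,b [line_segment()] objects.
#' @param tol Absolute coordinate tolerance for the closed-segment
#'   membership test.
#' @return Named numeric vector \code{c(x, y)}, or \code{NULL}.
#' @examples
#' intersect_segments(line_segment(35, 18, 45, 6),
#'                    line_segment(30, 8, 40, 17))   # x = 79/2.1 = 37.619...
#' @export
intersect_segments <- function(a, b, tol = 1e-9) {
  if (!inherits(a, "line_segment")) a <- do.call(line_segment, as.list(a))
  if (!inherits(b, "line_segment")) b <- do.call(line_segment, as.list(b))
  d1 <- c(a[["x2"]] - a[["x1"]], a[["y2"]] - a[["y1"]])
  d2 <- c(b[["x2"]] - b[["x1"]], b[["y2"]] - b[["y1"]])
  r  <- c(b[["x1"]] - a[["x1"]], b[["y1"]] - a[["y1"]])
  denom <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
  scale <- max(abs(c(d1, d2)), 1)
  if (abs(denom) <= 1e-12 * scale^2) {           # parallel
    if (abs(r[1L] * d1[2L] - r[2L] * d1[1L]) > tol * scale)
      return(NULL)                               # parallel, not collinear
    # collinear: overlap in the parameter of segment a
    along <- if (abs(d1[1L]) >= abs(d1[2L])) 1L else 2L
    t0 <- r[along] / d1[along]
    t1 <- t0 + d2[along] / d1[along]
    lo <- max(0, min(t0, t1)); hi <- min(1, max(t0, t1))
    if (lo > hi + tol / abs(d1[along])) return(NULL)
    ts <- c(lo, hi)
    px <- a[["x1"]] + ts * d1[1L]
    py <- a[["y1"]] + ts * d1[2L]
    pick <- if (abs(px[1L] - px[2L]) > tol) which.min(px) else which.min(py)
    return(c(x = px[pick], y = py[pick]))
  }
  t <- (r[1L] * d2[2L] - r[2L] * d2[1L]) / denom
  u <- (r[1L] * d1[2L] - r[2L] * d1[1L]) / denom
  p <- c(x = a[["x1"]] + t * d1[1L], y = a[["y1"]] + t * d1[2L])
  on_seg <- function(s, p)
    p[1L] >= min(s[["x1"]], s[["x2"]]) - tol &&
    p[1L] <= max(s[["x1"]], s[["x2"]]) + tol &&
    p[2L] >= min(s[["y1"]], s[["y2"]]) - tol &&
    p[2L] <= max(s[["y1"]], s[["y2"]]) + tol
  if (on_seg(a, p) && on_seg(b, p)) p else NULL
}

#' Round for display, half away from zero
#'
#' The cut-off is reported at two decimal places with halves rounded away
#' from zero (so 37.615 displays as 37.62), unlike base \code{round()}'s
#' round-half-even. Full precision is always retained internally.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
display_round <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Locate the Hofstee cut-off on the cumulative curve
#'
#' Scans the cumulative polyline's segments in ascending-x order and
#' returns the first whose intersection with the compromise line AB lies
#' on both closed segments. When the crossing coincides with a shared
#' vertex of two curve segments, both produce the identical point, so the
#' first suffices. When AB and the curve do not meet, the default is to
#' fail loudly with a directional diagnostic — the curve lying entirely
#' above AB means more students fail than the judges will accept, entirely
#' below means fewer — rather than silently substituting a corner of the
#' parameter box; \code{fallback = "corner"} opts into substituting the AB
#' endpoint nearer (in failure-rate distance) to the curve.
#'
#' @param c A [build_cumulative_curve()] result.
#' @param ab The compromise line from [hofstee_line()].
#' @param tol Absolute tolerance for segment membership (default 1e-9).
#' @param fallback \code{"none"} (default: no intersection is an error) or
#'   \code{"corner"}.
#' @return An object of class \code{"cutoff_result"}: a list with
#'   \code{cutoff_x} (the cut-off score, full precision), \code{cutoff_y}
#'   (expected percent failing), \code{segment_index} (which curve segment
#'   produced the crossing; \code{NA} for a corner fallback),
#'   \code{display_cutoff} and \code{display_fail} (2 dp, half away from
#'   zero), and \code{fallback} (logical).
#' @examples
#' s <- score_set(c(5, 8, 12, 15, 18, 22, 26, 30, rep(40, 9), 41:83))
#' cv <- build_cumulative_curve(s)
#' find_cutoff(cv, hofstee_line(hofstee_params(35, 45, 6, 18)))
#' @export
find_cutoff <- function(c, ab, tol = 1e-9, fallback = c("none", "corner")) {
  fallback <- match.arg(fallback)
  m <- nrow(c)
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) {
      seg <- line_segment(c$x[i], c$y[i], c$x[i + 1L], c$y[i + 1L])
      p <- intersect_segments(ab, seg, tol = tol)
      if (!is.null(p))
        return(cutoff_result(p[["x"]], p[["y"]], i))
    }
  } else {
    # single distinct score: the "curve" is one point
    p <- intersect_segments(ab, line_segment(c$x[1L] - tol, c$y[1L],
                                             c$x[1L] + tol, c$y[1L]),
                            tol = tol)
    if (!is.null(p)) return(cutoff_result(c$x[1L], c$y[1L], 1L))
  }
  diag <- no_intersection_diagnostic(c, ab)
  if (fallback == "corner") {
    ends <- rbind(A = c(ab[["x1"]], ab[["y1"]]), B = c(ab[["x2"]], ab[["y2"]]))
    rng <- range(c$x)
    ydist <- apply(ends, 1L, function(e) {
      if (e[1L] >= rng[1L] && e[1L] <= rng[2L])
        abs(curve_value_at(c, e[1L]) - e[2L]) else Inf
    })
    pick <- if (all(!is.finite(ydist))) {
      xdist <- pmin(abs(ends[, 1L] - rng[1L]), abs(ends[, 1L] - rng[2L]))
      which.min(xdist)
    } else which.min(ydist)
    res <- cutoff_result(ends[pick, 1L], ends[pick, 2L], NA_integer_,
                         fallback = TRUE)
    res$diagnostic <- diag
    return(res)
  }
  stop(sprintf("no intersection between line AB and the cumulative curve: %s",
               diag), call. = FALSE)
}

cutoff_result <- function(x, y, segment_index, fallback = FALSE) {
  structure(list(cutoff_x = x, cutoff_y = y,
                 segment_index = segment_index,
                 display_cutoff = display_round(x),
                 display_fail = display_round(y),
                 fallback = fallback),
            class = "cutoff_result")
}

no_intersection_diagnostic <- function(c, ab) {
  crng <- range(c$x)
  arng <- range(ab[c("x1", "x2")])
  if (crng[1L] > arng[2L])
    return(paste("all observed scores lie above c_max, the curve is entirely",
                 "below AB: too few students failing in the parameter window;",
                 "consider raising c_max or lowering f_min"))
  if (crng[2L] < arng[1L])
    return(paste("all observed scores lie below c_min, the curve is entirely",
                 "above AB: too many students failing in the parameter window;",
                 "consider lowering c_min or raising f_max"))
  ov <- c(max(crng[1L], arng[1L]), min(crng[2L], arng[2L]))
  xs <- unique(c(ov, c$x[c$x >= ov[1L] & c$x <= ov[2L]]))
  ab_y <- ab_value_at(ab, xs)
  d <- curve_value_at(c, xs) - ab_y
  if (all(d > 0))
    paste("the cumulative curve lies entirely above AB: too many students",
          "failing; consider raising f_max or lowering c_min")
  else
    paste("the cumulative curve lies entirely below AB: too few students",
          "failing; consider lowering f_min or raising c_max")
}

# y-value of a (non-vertical) segment's supporting line at x
ab_value_at <- function(ab, x) {
  if (ab[["x1"]] == ab[["x2"]]) return(rep(mean(ab[c("y1", "y2")]), length(x)))
  ab[["y1"]] + (x - ab[["x1"]]) *
    (ab[["y2"]] - ab[["y1"]]) / (ab[["x2"]] - ab[["x1"]])
}

#' @export
print.cutoff_result <- function(x, ...) {
  if (isTRUE(x$fallback))
    cat("Hofstee cut-off (corner fallback - no true intersection):\n")
  else
    cat("Hofstee cut-off:\n")
  cat(sprintf("  cut-off score: %.2f (full precision %.10g)\n",
              x$display_cutoff, x$cutoff_x))
  cat(sprintf("  expected failing: %.2f%% of students\n", x$display_fail))
  if (!is.na(x$segment_index))
    cat(sprintf("  crossing on cumulative segment #%d\n", x$segment_index))
  invisible(x)
}
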