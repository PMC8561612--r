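#' Fit a Hofstee compromise standard to a score distribution
#'
#' The one-stop interface: takes the raw scores and the judges' parameters,
#' aggregates the panel, builds the cumulative percentage curve, constructs
#' the compromise line AB from (c_min, f_max) to (c_max, f_min), locates
#' the cut-off as their intersection, and reports the largest score gaps
#' in the parameter window.
#'
#' The Hofstee method reconciles an absolute (criterion-referenced)
#' standard with a relative (norm-referenced) one: the judges bound the
#' plausible cut-off score by \[c_min, c_max\] and the tolerable failure
#' rate by \[f_min, f_max\], and the observed distribution picks the
#' compromise point where the cumulative curve crosses AB.
#'
#' @param scores A [score_set()], a numeric vector of scores, or a path to
#'   a single-column CSV file (read via [read_scores()]).
#' @param judges A list of per-judge quadruples \code{c(c_min, c_max,
#'   f_min, f_max)} (or [judge_estimate()] objects), or a ready-made
#'   [judge_panel()]. Ignored when \code{params} is given.
#' @param params A direct quadruple \code{c(c_min, c_max, f_min, f_max)}
#'   or [hofstee_params()] object, for when aggregation happened
#'   elsewhere.
#' @param method Panel aggregation: \code{"mean"} (default) or
#'   \code{"median"}.
#' @param gap_window Score window for the gap report; default
#'   \code{c(c_min, c_max)} after aggregation.
#' @param top_gaps Number of gaps reported (default 3).
#' @param fallback Passed to [find_cutoff()]: \code{"none"} (default) or
#'   \code{"corner"}.
#' @return An object of class \code{"hofstee"}: a list with components
#'   \code{scores}, \code{panel} (or \code{NULL} for direct parameters),
#'   \code{params}, \code{line}, \code{curve}, \code{cutoff}
#'   (a \code{cutoff_result}) and \code{gaps}.
#' @examples
#' fit <- hofstee(c(5, 8, 12, 15, 18, 22, 26, 30, rep(40, 9), 41:83),
#'                params = c(35, 45, 6, 18))
#' fit
#' coef(fit)
#' @seealso [find_cutoff()], [aggregate_panel()], [plot.hofstee()]
#' @export
hofstee <- function(scores, judges = NULL, params = NULL,
                    method = c("mean", "median"),
                    gap_window = NULL, top_gaps = 3L,
                    fallback = c("none", "corner")) {
  method <- match.arg(method)
  fallback <- match.arg(fallback)
  s <- if (inherits(scores, "score_set")) scores
       else if (is.character(scores) && length(scores) == 1L) read_scores(scores)
       else score_set(scores)
  panel <- NULL
  if (!is.null(params)) {
    p <- if (inherits(params, "hofstee_params")) params
         else hofstee_params(params[[1L]], params[[2L]], params[[3L]],
                             params[[4L]], source = "direct")
  } else if (!is.null(judges)) {
    panel <- if (inherits(judges, "judge_panel")) judges else judge_panel(judges)
    p <- aggregate_panel(panel, method)
  } else {
    stop("supply either 'judges' or 'params'", call. = FALSE)
  }
  ab <- hofstee_line(p)
  cv <- build_cumulative_curve(s)
  cut <- find_cutoff(cv, ab, fallback = fallback)
  if (is.null(gap_window)) gap_window <- c(p[["c_min"]], p[["c_max"]])
  gaps <- if (gap_window[1L] < gap_window[2L])
    find_gaps(s, gap_window[1L], gap_window[2L], top_k = top_gaps)
  else
    find_gaps(s, gap_window[1L] - 1, gap_window[2L] + 1, top_k = top_gaps)
  structure(list(scores = s, panel = panel, params = p, line = ab,
                 curve = cv, cutoff = cut, gaps = gaps,
                 method = if (is.null(panel)) "direct" else method),
            class = "hofstee")
}

#' @export
print.hofstee <- function(x, ...) {
  cat(sprintf("Hofstee compromise standard (n = %d students)\n\n",
              attr(x$scores, "n")))
  print(x$params)
  cat("\n")
  print(x$cutoff)
  invisible(x)
}

#' @export
summary.hofstee <- function(object, ...) {
  structure(list(fit = object), class = "summary.hofstee")
}

#' @export
print.summary.hofstee <- function(x, ...) {
  f <- x$fit
  print(f)
  if (!is.null(f$panel)) {
    cat("\n")
    print(f$panel)
  }
  cat("\n")
  print(f$gaps)
  n <- attr(f$scores, "n")
  n_fail <- sum(as.numeric(f$scores) < f$cutoff$cutoff_x)
  cat(sprintf("\nStudents below the cut-off: %d of %d (%.2f%%)\n",
              n_fail, n, 100 * n_fail / n))
  invisible(x)
}

#' Extract the fitted Hofstee quantities
#'
#' @param object A fitted \code{"hofstee"} object.
#' @param ... Unused.
#' @return Named numeric vector: the four aggregated parameters, the
#'   cut-off score and the expected percent failing.
#' @export
coef.hofstee <- function(object, ...) {
  c(unclass(object$params)[c("c_min", "c_max", "f_min", "f_max")],
    cutoff = object$cutoff$cutoff_x,
    expected_fail = object$cutoff$cutoff_y)
}

#' Cumulative percent at given scores, from the fitted curve
#'
#' @param object A fitted \code{"hofstee"} object.
#' @param newdata Scores at which to evaluate the cumulative curve;
#'   default: the cut-off score.
#' @param ... Unused.
#' @return Cumulative percent of students at or below each score.
#' @export
predict.hofstee <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$cutoff$cutoff_x
  curve_value_at(object$curve, newdata)
}

#' Serialise a fitted Hofstee standard to a JSON document
#'
#' Machine-readable companion to the printed summary: the cut-off (full
#' precision and 2 dp display), the expected failure rate, the parameter
#' set and its provenance, the gap report and any diagnostics. Output is
#' deterministic — re-running on the same inputs yields byte-identical
#' JSON.
#'
#' @param fit A fitted \code{"hofstee"} object.
#' @param path Optional file path; when \code{NULL} the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to \code{path}).
#' @export
hofstee_json <- function(fit, path = NULL) {
  p <- fit$params
  doc <- list(
    cutoff = fit$cutoff$cutoff_x,
    cutoff_display = fit$cutoff$display_cutoff,
    expected_fail_percent = fit$cutoff$cutoff_y,
    expected_fail_display = fit$cutoff$display_fail,
    n_students = attr(fit$scores, "n"),
    parameters = as.list(unclass(p)[c("c_min", "c_max", "f_min", "f_max")]),
    aggregation_method = fit$method,
    segment_index = fit$cutoff$segment_index,
    fallback_used = isTRUE(fit$cutoff$fallback),
    gaps = if (nrow(fit$gaps) == 0L) list() else
      lapply(seq_len(nrow(fit$gaps)), function(i)
        list(lower = fit$gaps$lower[i], upper = fit$gaps$upper[i],
             width = fit$gaps$width[i])),
    diagnostics = if (is.null(fit$cutoff$diagnostic)) NULL
                  else fit$cutoff$diagnostic
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(as.character(json))
}
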