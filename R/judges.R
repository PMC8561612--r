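#' Create and validate a single judge's Hofstee estimate
#'
#' A judge supplies four bounds: \code{c_min}/\code{c_max}, the lowest and
#' highest score the judge would accept as the pass/fail cut-off, and
#' \code{f_min}/\code{f_max}, the lowest and highest percentage of students
#' the judge would accept failing. All four are percentages in \[0, 100\],
#' with \code{c_min <= c_max} and \code{f_min <= f_max}. Non-integer values
#' are accepted, so pre-aggregated bounds (e.g. 53.5) can be entered
#' directly.
#'
#' @param c_min Minimum acceptable cut-off score (percent, 0-100).
#' @param c_max Maximum acceptable cut-off score (percent, 0-100).
#' @param f_min Minimum acceptable failure rate (percent of students, 0-100).
#' @param f_max Maximum acceptable failure rate (percent of students, 0-100).
#' @param judge_id Optional positive integer identifying the judge.
#'
#' @return An object of class \code{"judge_estimate"}: a named numeric
#'   vector with elements \code{c_min}, \code{c_max}, \code{f_min},
#'   \code{f_max} and a \code{judge_id} attribute.
#' @examples
#' judge_estimate(35, 45, 6, 18)
#' @export
judge_estimate <- function(c_min, c_max, f_min, f_max, judge_id = NA_integer_) {
  vals <- c(c_min = c_min, c_max = c_max, f_min = f_min, f_max = f_max)
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals)))
    stop("judge estimate: all four parameters must be finite numbers",
         call. = FALSE)
  structure(as.numeric(vals),
            names = names(vals),
            judge_id = judge_id,
            class = "judge_estimate")
}

#' Validate a judge estimate against the Hofstee parameter invariants
#'
#' Checks range (\[0, 100\]) and ordering (\code{c_min <= c_max},
#' \code{f_min <= f_max}) and reports exactly which invariant failed.
#'
#' @param e A \code{judge_estimate} or a numeric vector of length four in
#'   the order \code{c_min, c_max, f_min, f_max}.
#' @return The validated \code{judge_estimate}, unchanged.
#' @export
validate_estimate <- function(e) {
  if (!inherits(e, "judge_estimate")) {
    if (!is.numeric(e) || length(e) != 4L)
      stop("judge estimate must be four numbers: c_min, c_max, f_min, f_max",
           call. = FALSE)
    e <- judge_estimate(e[[1L]], e[[2L]], e[[3L]], e[[4L]])
  }
  who <- attr(e, "judge_id")
  tag <- if (is.na(who)) "" else sprintf(" (judge %s)", who)
  if (any(e < 0 | e > 100)) {
    bad <- names(e)[e < 0 | e > 100]
    stop(sprintf("range violation%s: %s outside [0, 100]",
                 tag, paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (e[["c_min"]] > e[["c_max"]])
    stop(sprintf("ordering violation%s: c_min > c_max (%g > %g)",
                 tag, e[["c_min"]], e[["c_max"]]), call. = FALSE)
  if (e[["f_min"]] > e[["f_max"]])
    stop(sprintf("ordering violation%s: f_min > f_max (%g > %g)",
                 tag, e[["f_min"]], e[["f_max"]]), call. = FALSE)
  e
}

#' Assemble a panel of judges
#'
#' Collects one estimate per judge and computes per-parameter aggregation
#' statistics: mean, sample standard deviation (n - 1 denominator) and
#' median. The panel is the unit the compromise line is built from; the
#' method itself places no upper limit on the number of judges, though in
#' practice panels rarely exceed ten.
#'
#' @param ... \code{judge_estimate} objects, numeric length-4 vectors, or a
#'   single list of either. Each is validated on entry.
#' @return An object of class \code{"judge_panel"}: a list with
#'   \code{estimates} (a numeric matrix, one row per judge, columns
#'   \code{c_min, c_max, f_min, f_max}) and \code{stats} (a matrix with rows
#'   \code{mean}, \code{sd}, \code{median}).
#' @examples
#' judge_panel(c(50, 60, 1, 4), c(44, 56, 3, 8), c(41, 52, 4, 8))
#' @export
judge_panel <- function(...) {
  ests <- list(...)
  if (length(ests) == 1L && is.list(ests[[1L]]) &&
      !inherits(ests[[1L]], "judge_estimate"))
    ests <- ests[[1L]]
  if (length(ests) == 0L)
    stop("judge panel must contain at least one estimate", call. = FALSE)
  ests <- lapply(seq_along(ests), function(i) {
    e <- ests[[i]]
    if (!inherits(e, "judge_estimate")) {
      e <- judge_estimate(e[[1L]], e[[2L]], e[[3L]], e[[4L]], judge_id = i)
    } else if (is.na(attr(e, "judge_id"))) {
      attr(e, "judge_id") <- i
    }
    validate_estimate(e)
  })
  m <- do.call(rbind, lapply(ests, unclass))
  rownames(m) <- vapply(ests, function(e) as.character(attr(e, "judge_id")), "")
  structure(list(estimates = m, stats = panel_stats(m)),
            class = "judge_panel")
}

panel_stats <- function(m) {
  rbind(mean   = colMeans(m),
        sd     = if (nrow(m) > 1L) apply(m, 2L, stats::sd) else
                   c(c_min = 0, c_max = 0, f_min = 0, f_max = 0),
        median = apply(m, 2L, stats::median))
}

#' @export
print.judge_panel <- function(x, ...) {
  cat(sprintf("Hofstee judge panel: %d judge%s\n", nrow(x$estimates),
              if (nrow(x$estimates) == 1L) "" else "s"))
  print(round(x$estimates, 2))
  cat("\nPer-parameter aggregates:\n")
  print(round(x$stats, 2))
  invisible(x)
}

#' Aggregate a judge panel into a single parameter set
#'
#' Reduces the panel to one quadruple by taking the arithmetic mean
#' (the method's standard choice) or the median (the usual robust
#' alternative) of each parameter across judges. For an even number of
#' judges the median is the mean of the two middle values. Sample standard
#' deviations are carried along for reporting.
#'
#' @param panel A \code{judge_panel}.
#' @param method \code{"mean"} (default) or \code{"median"}.
#' @return A \code{hofstee_params} object (see [hofstee_params()]) with the
#'   panel's standard deviations attached as attribute \code{"sd"}.
#' @examples
#' p <- judge_panel(c(50, 60, 1, 4), c(44, 56, 3, 8), c(41, 52, 4, 8),
#'                  c(45, 54, 5, 8), c(45, 53, 2, 7))
#' aggregate_panel(p)             # means: (45, 55, 3, 7)
#' aggregate_panel(p, "median")
#' @export
aggregate_panel <- function(panel, method = c("mean", "median")) {
  method <- match.arg(method)
  if (!inherits(panel, "judge_panel"))
    stop("'panel' must be a judge_panel", call. = FALSE)
  agg <- panel$stats[method, ]
  # means/medians preserve per-judge orderings, so this cannot trigger for
  # a validated panel
  stopifnot(agg[["c_min"]] <= agg[["c_max"]], agg[["f_min"]] <= agg[["f_max"]])
  p <- hofstee_params(agg[["c_min"]], agg[["c_max"]],
                      agg[["f_min"]], agg[["f_max"]], source = method)
  attr(p, "sd") <- panel$stats["sd", ]
  attr(p, "n_judges") <- nrow(panel$estimates)
  p
}

#' Aggregated Hofstee parameters
#'
#' The single quadruple that defines the compromise line AB, either
#' aggregated from a panel ([aggregate_panel()]) or entered directly when
#' the judges' values were combined elsewhere.
#'
#' @inheritParams judge_estimate
#' @param source How the values were obtained: \code{"mean"},
#'   \code{"median"} or \code{"direct"}.
#' @return An object of class \code{"hofstee_params"}: a named numeric
#'   vector \code{c_min, c_max, f_min, f_max} with a \code{source}
#'   attribute.
#' @examples
#' hofstee_params(35, 45, 6, 18)
#' @export
hofstee_params <- function(c_min, c_max, f_min, f_max,
                           source = c("direct", "mean", "median")) {
  source <- match.arg(source)
  e <- validate_estimate(judge_estimate(c_min, c_max, f_min, f_max))
  structure(unclass(e), judge_id = NULL, source = source,
            class = "hofstee_params")
}

#' @export
print.hofstee_params <- function(x, ...) {
  cat(sprintf("Hofstee parameters (%s):\n", attr(x, "source")))
  cat(sprintf("  cut-off score bounds  c_min = %g, c_max = %g\n",
              x[["c_min"]], x[["c_max"]]))
  cat(sprintf("  failure-rate bounds   f_min = %g, f_max = %g\n",
              x[["f_min"]], x[["f_max"]]))
  sd <- attr(x, "sd")
  if (!is.null(sd))
    cat(sprintf("  panel SDs: %s\n",
                paste(sprintf("%s %.2f", names(sd), sd), collapse = ", ")))
  invisible(x)
}
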