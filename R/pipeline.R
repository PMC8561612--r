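#' Read a Hofstee run configuration file
#'
#' YAML key-value schema, the file-based replacement for the app habit of
#' remembering the last-entered parameters:
#' \preformatted{
#' judges:            # optional: one 4-vector per judge
#'   - [50, 60, 1, 4]
#'   - [44, 56, 3, 8]
#' params: [45, 55, 3, 7]   # optional: direct aggregate quadruple
#' method: mean             # mean | median
#' }
#' \code{params} takes precedence over \code{judges} when both are
#' present.
#'
#' @param path Path to the YAML file.
#' @return A list with elements \code{judges}, \code{params},
#'   \code{method} (NULL when absent).
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  list(judges = cfg$judges, params = unlist(cfg$params),
       method = cfg$method)
}

#' Write a Hofstee run configuration file
#'
#' @param path Output path.
#' @param judges Optional list of per-judge quadruples.
#' @param params Optional direct quadruple.
#' @param method Aggregation method to record.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(path, judges = NULL, params = NULL,
                         method = "mean") {
  cfg <- list()
  if (!is.null(judges)) cfg$judges <- lapply(judges, as.numeric)
  if (!is.null(params)) cfg$params <- as.numeric(params)
  cfg$method <- method
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Exit/status codes used by the pipeline and CLI
#'
#' 0 success; 2 input error (missing/unreadable/empty file, non-numeric
#' cell); 3 validation error (parameter range or ordering); 4 no
#' intersection between AB and the curve.
#'
#' @format Named integer vector.
#' @export
hofstee_status <- c(ok = 0L, input_error = 2L, validation_error = 3L,
                    no_intersection = 4L)

#' Run the full Hofstee pipeline: read, aggregate, intersect, report
#'
#' The programmatic equivalent of the app workflow and the engine behind
#' the command-line interface: read scores, aggregate the judges (or take
#' direct parameters), build the curve, locate the cut-off, report gaps,
#' and optionally write the JSON result, charts and the curve CSV.
#' Errors do not throw; they are mapped to a status code (see
#' [hofstee_status]) so shell callers get a distinct exit code per error
#' class, and no partial outputs are written on failure.
#'
#' @param scores Path to the scores CSV (or a numeric vector /
#'   [score_set()]).
#' @param judges,params,method,fallback,top_gaps As in [hofstee()];
#'   \code{config} (path to a [read_config()] file) may supply
#'   judges/params/method instead, with explicit arguments winning.
#' @param config Optional path to a YAML configuration file.
#' @param json Optional path for the JSON result document.
#' @param chart \code{"none"}, \code{"full"}, \code{"detailed"} or
#'   \code{"both"}.
#' @param out_dir Directory for chart output (created if needed);
#'   default \code{"."}.
#' @param chart_format \code{"png"} or \code{"svg"}.
#' @param curve_csv Optional path for the audit CSV of curve vertices.
#' @param quiet Suppress the printed summary.
#' @return A list with \code{status} (integer code), \code{fit} (the
#'   \code{"hofstee"} object, or NULL on failure), \code{error} (message
#'   or NULL) and \code{outputs} (character vector of files written).
#' @export
run_pipeline <- function(scores, judges = NULL, params = NULL,
                         method = "mean", config = NULL,
                         json = NULL, chart = c("none", "full", "detailed", "both"),
                         out_dir = ".", chart_format = "png",
                         curve_csv = NULL, fallback = "none",
                         top_gaps = 3L, quiet = FALSE) {
  chart <- match.arg(chart)
  fail <- function(code, e)
    list(status = hofstee_status[[code]], fit = NULL,
         error = conditionMessage(e), outputs = character(0))

  if (!is.null(config)) {
    cfg <- tryCatch(read_config(config), error = function(e) e)
    if (inherits(cfg, "error")) return(fail("input_error", cfg))
    if (is.null(judges) && is.null(params)) {
      judges <- cfg$judges
      params <- cfg$params
    }
    if (!is.null(cfg$method) && missing(method)) method <- cfg$method
  }

  s <- tryCatch({
    if (inherits(scores, "score_set")) scores
    else if (is.character(scores)) read_scores(scores)
    else score_set(scores)
  }, error = function(e) e)
  if (inherits(s, "error")) return(fail("input_error", s))

  if (!is.null(judges) && length(judges) > 10L)
    warning(sprintf("panel of %d judges; Hofstee panels rarely exceed 10",
                    length(judges)), call. = FALSE)

  fit <- tryCatch(
    hofstee(s, judges = judges, params = params, method = method,
            top_gaps = top_gaps, fallback = fallback),
    error = function(e) e)
  if (inherits(fit, "error")) {
    code <- if (grepl("no intersection", conditionMessage(fit)))
      "no_intersection" else "validation_error"
    return(fail(code, fit))
  }

  outputs <- character(0)
  if (!is.null(json)) {
    hofstee_json(fit, json)
    outputs <- c(outputs, json)
  }
  if (!is.null(curve_csv)) {
    write_curve(fit$curve, curve_csv)
    outputs <- c(outputs, curve_csv)
  }
  if (chart != "none") {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    modes <- if (chart == "both") c("full", "detailed") else chart
    for (m in modes) {
      f <- file.path(out_dir, sprintf("hofstee_%s.%s", m, chart_format))
      render_chart(fit$curve, fit$line, fit$cutoff, f, mode = m,
                   format = chart_format)
      outputs <- c(outputs, f)
    }
  }
  if (!quiet) print(summary(fit))
  list(status = hofstee_status[["ok"]], fit = fit, error = NULL,
       outputs = outputs)
}
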