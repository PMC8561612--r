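#' Construct a validated score set
#'
#' Scores are percentages in \[0, 100\]; anything outside that range is an
#' error rather than a warning, because the Hofstee chart's axes are
#' percentage axes and silently clipping a score would corrupt the
#' cut-off. Duplicates are retained (they shape the cumulative curve) and
#' the set is stored sorted ascending.
#'
#' @param scores Numeric vector of raw scores, any order.
#' @param source_label Free-text provenance recorded with the set.
#' @return An object of class \code{"score_set"}: the sorted numeric vector
#'   with attributes \code{n} and \code{source_label}.
#' @examples
#' score_set(c(97, 43, 50))
#' @export
score_set <- function(scores, source_label = "in-memory") {
  if (length(scores) == 0L)
    stop("score set must contain at least one score", call. = FALSE)
  if (!is.numeric(scores) || anyNA(scores) || any(!is.finite(scores)))
    stop("scores must all be finite numbers", call. = FALSE)
  if (any(scores < 0 | scores > 100)) {
    bad <- which(scores < 0 | scores > 100)[1L]
    stop(sprintf("score outside [0, 100]: %g", scores[bad]), call. = FALSE)
  }
  structure(sort(as.numeric(scores)),
            n = length(scores), source_label = source_label,
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("Score set (%s): n = %d, range %g-%g, %d distinct values\n",
              attr(x, "source_label"), attr(x, "n"),
              min(x), max(x), length(unique(unclass(x)))))
  invisible(x)
}

#' Read student scores from a single-column CSV file
#'
#' Only the first column is read; any further columns are ignored, so
#' gradebook exports with extra metadata work unchanged. Exactly one
#' leading non-numeric row is tolerated as a header. Input order is
#' irrelevant: the scores are sorted on read. The CSV dialect is
#' comma-delimited with point decimal separators; CRLF and LF line endings
#' are both accepted.
#'
#' @param path Path to the CSV file.
#' @param max_rows Optional cap on the number of data rows read
#'   (default: unlimited).
#' @return A [score_set()] whose \code{source_label} is the file path.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("score", "43", "97", "50"), f)
#' read_scores(f)
#' @export
read_scores <- function(path, max_rows = Inf) {
  if (!file.exists(path))
    stop(sprintf("scores file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop(sprintf("no data in scores file: %s", path), call. = FALSE)
  first_col <- trimws(vapply(strsplit(lines, ",", fixed = TRUE),
                             `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(first_col))
  header_skipped <- FALSE
  if (is.na(vals[1L])) {            # one leading header row is tolerated
    vals <- vals[-1L]
    lines <- lines[-1L]
    header_skipped <- TRUE
  }
  if (length(vals) == 0L)
    stop(sprintf("no numeric rows in scores file: %s", path), call. = FALSE)
  if (anyNA(vals)) {
    row <- which(is.na(vals))[1L]
    stop(sprintf("non-numeric value in %s at data row %d: '%s'",
                 path, row, lines[row]), call. = FALSE)
  }
  if (is.finite(max_rows) && length(vals) > max_rows)
    vals <- vals[seq_len(max_rows)]
  score_set(vals, source_label = path)
}

#' Generate a synthetic uniform score set
#'
#' Draws \code{n} integer scores uniformly (with replacement) from
#' \code{[low, high]}, mirroring the spreadsheet-style
#' \code{RANDBETWEEN(low, high)} fixtures used to exercise the method at
#' scale. Identical \code{(n, low, high, seed)} reproduce the identical
#' set.
#'
#' @param n Number of scores to draw (positive integer).
#' @param low,high Inclusive integer bounds, \code{0 <= low <= high <= 100}.
#' @param seed Integer seed; the draw is isolated from the caller's RNG
#'   state.
#' @return A [score_set()] labelled with the generation parameters.
#' @examples
#' generate_synthetic_scores(10, 1, 100, seed = 42)
#' @export
generate_synthetic_scores <- function(n, low = 1L, high = 100L, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0 || n != floor(n))
    stop("n must be a positive integer", call. = FALSE)
  if (low > high) stop("low must not exceed high", call. = FALSE)
  if (low < 0 || high > 100)
    stop("bounds must lie within [0, 100]", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  vals <- sample.int(high - low + 1L, size = n, replace = TRUE) + low - 1L
  score_set(vals,
            source_label = sprintf("synthetic uniform [%d,%d], n=%d, seed=%d",
                                   low, high, as.integer(n), as.integer(seed)))
}

#' Write a score set to a single-column CSV fixture
#'
#' @param s A [score_set()].
#' @param path Output file path.
#' @param shuffle_seed If non-NULL, write the rows in a seeded random order
#'   (the reader sorts, so this exercises order-independence).
#' @return \code{path}, invisibly.
#' @export
write_scores <- function(s, path, shuffle_seed = NULL) {
  vals <- as.numeric(s)
  if (!is.null(shuffle_seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(shuffle_seed))
    vals <- sample(vals)
  }
  writeLines(format(vals, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}
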