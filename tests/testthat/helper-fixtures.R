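# Fixture builders and independent oracles shared across the suite.

# 100-student cohort whose cumulative curve contains the exact segment
# (30, 8)-(40, 17): 8 distinct scores up to 30, nine students tied at 40,
# then 83 distinct scores above 40.
fig1_style_scores <- function() {
  score_set(c(5, 8, 12, 15, 18, 22, 26, 30,
              rep(40, 9),
              seq(41, 97, length.out = 83)),
            source_label = "synthetic fig1-style cohort")
}

# Synthetic 181-student cohort with the published characteristics of the
# use-case class: range 43-97, 6th and 7th ascending scores 53.5 and 54.5,
# all other scores distinct. Its curve contains the vertices
# (53.5, 100*6/181) and (54.5, 100*7/181).
use_case_style_scores <- function() {
  score_set(c(43, 44, 46, 48, 50, 53.5, 54.5,
              seq(55, 97, length.out = 174)),
            source_label = "synthetic use-case cohort")
}

# Published judge panel for the use case (five raters).
use_case_panel <- function() {
  judge_panel(c(50, 60, 1, 4), c(44, 56, 3, 8), c(41, 52, 4, 8),
              c(45, 54, 5, 8), c(45, 53, 2, 7))
}

# Brute-force cut-off oracle, independent of the segment scan: dense grid
# over the overlap of the curve's x-range with [c_min, c_max], first sign
# change of curve(x) - AB(x), refined by bisection. Assumes AB is not
# vertical. Returns the crossing x, or NULL.
brute_force_cutoff <- function(curve, ab, step = 1e-4) {
  ab_y <- function(x) ab[["y1"]] + (x - ab[["x1"]]) *
    (ab[["y2"]] - ab[["y1"]]) / (ab[["x2"]] - ab[["x1"]])
  lo <- max(min(curve$x), min(ab[c("x1", "x2")]))
  hi <- min(max(curve$x), max(ab[c("x1", "x2")]))
  if (lo > hi) return(NULL)
  xs <- seq(lo, hi, by = step)
  if (xs[length(xs)] < hi) xs <- c(xs, hi)
  f <- curve_value_at(curve, xs) - ab_y(xs)
  if (abs(f[1L]) < 1e-12) return(lo)
  i <- which(f[-length(f)] * f[-1L] <= 0)
  if (length(i) == 0L) return(NULL)
  a <- xs[i[1L]]; b <- xs[i[1L] + 1L]
  fa <- f[i[1L]]
  for (iter in 1:60) {
    m <- (a + b) / 2
    fm <- curve_value_at(curve, m) - ab_y(m)
    if (fa * fm <= 0) b <- m else { a <- m; fa <- fm }
  }
  (a + b) / 2
}

# Seeded random score-set / parameter configuration for property tests.
random_config <- function(seed) {
  set.seed(seed)
  n <- sample(30:300, 1L)
  scores <- score_set(round(runif(n, 0, 100), 1))
  c_min <- runif(1, 10, 70)
  c_max <- min(c_min + runif(1, 2, 25), 100)
  f_max <- runif(1, 5, 60)
  f_min <- runif(1, 0, f_max - 0.5)
  list(scores = scores,
       params = hofstee_params(c_min, c_max, f_min, f_max))
}

# find_cutoff with the no-intersection error mapped to NULL.
try_cutoff <- function(curve, ab) {
  tryCatch(find_cutoff(curve, ab),
           error = function(e) {
             if (grepl("no intersection", conditionMessage(e))) NULL
             else stop(e)
           })
}
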