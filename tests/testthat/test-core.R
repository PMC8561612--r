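test_that("line AB runs from (c_min, f_max) to (c_max, f_min)", {
  ab <- hofstee_line(hofstee_params(35, 45, 6, 18))
  expect_equal(unname(unclass(ab)), c(35, 18, 45, 6))
  ab2 <- hofstee_line(hofstee_params(45, 55, 3, 7))
  expect_equal(unname(unclass(ab2)), c(45, 7, 55, 3))
  # vertical when the score bounds coincide
  abv <- hofstee_line(hofstee_params(40, 40, 5, 15))
  expect_equal(unname(unclass(abv)), c(40, 15, 40, 5))
  expect_error(hofstee_line(hofstee_params(40, 40, 5, 5)), "AB is a point")
})

test_that("segment intersection reproduces both published crossings", {
  # closed form: 60 - 1.2x = 0.9x - 19  =>  x = 79/2.1
  p1 <- intersect_segments(line_segment(35, 18, 45, 6),
                           line_segment(30, 8, 40, 17))
  expect_equal(p1[["x"]], 79 / 2.1, tolerance = 1e-12)
  expect_equal(display_round(p1[["x"]]), 37.62)

  p2 <- intersect_segments(line_segment(45, 7, 55, 3),
                           line_segment(53.5, 3.31, 54.5, 3.87))
  expect_equal(display_round(p2[["x"]]), 53.80)
})

test_that("segment intersection handles parallel, disjoint, collinear and endpoint cases", {
  expect_null(intersect_segments(line_segment(0, 0, 1, 1),
                                 line_segment(0, 1, 1, 2)))
  # lines cross but outside the closed segments
  expect_null(intersect_segments(line_segment(0, 0, 1, 1),
                                 line_segment(3, 0, 4, 5)))
  # collinear overlap: smallest-x point of the overlap
  p <- intersect_segments(line_segment(0, 0, 10, 10),
                          line_segment(4, 4, 20, 20))
  expect_equal(unname(p), c(4, 4))
  # collinear without overlap
  expect_null(intersect_segments(line_segment(0, 0, 1, 1),
                                 line_segment(2, 2, 3, 3)))
  # vertical collinear overlap: smallest-y point
  pv <- intersect_segments(line_segment(5, 0, 5, 10),
                           line_segment(5, 6, 5, 20))
  expect_equal(unname(pv), c(5, 6))
  # shared endpoint counts as an intersection
  pe <- intersect_segments(line_segment(0, 0, 1, 1),
                           line_segment(1, 1, 2, 0))
  expect_equal(unname(pe), c(1, 1))
  expect_error(line_segment(1, 1, 1, 1), "degenerate")
})

test_that("display rounding is half away from zero at 2 dp", {
  expect_equal(display_round(37.615), 37.62)
  expect_equal(display_round(2.675), 2.68)
  expect_equal(display_round(-2.675), -2.68)
  expect_equal(display_round(79 / 2.1), 37.62)
  expect_equal(display_round(53.8020833), 53.80)
})

test_that("find_cutoff reproduces the worked examples end to end", {
  fit_ab <- hofstee_line(hofstee_params(35, 45, 6, 18))
  cv <- build_cumulative_curve(fig1_style_scores())
  r <- find_cutoff(cv, fit_ab)
  expect_equal(r$display_cutoff, 37.62)
  expect_equal(r$cutoff_x, 79 / 2.1, tolerance = 1e-9)
  expect_equal(r$cutoff_y, curve_value_at(cv, r$cutoff_x), tolerance = 1e-9)
  expect_true(r$cutoff_x >= 35 && r$cutoff_x <= 45)
  expect_true(r$cutoff_y >= 6 && r$cutoff_y <= 18)

  ab2 <- hofstee_line(aggregate_panel(use_case_panel(), "mean"))
  r2 <- find_cutoff(build_cumulative_curve(use_case_style_scores()), ab2)
  expect_equal(r2$display_cutoff, 53.80)
})

test_that("a crossing at a shared vertex is found and identical from either segment", {
  # curve [10,20,30] of 3 students: vertex (20, 200/3); AB through it
  cv <- build_cumulative_curve(score_set(c(10, 20, 30)))
  y0 <- 200 / 3
  ab <- line_segment(15, y0 + 5, 25, y0 - 5)  # passes exactly through (20, y0)
  p_left <- intersect_segments(ab, line_segment(10, 100 / 3, 20, y0))
  p_right <- intersect_segments(ab, line_segment(20, y0, 30, 100))
  expect_equal(p_left[["x"]], 20, tolerance = 1e-9)
  expect_equal(p_right[["x"]], 20, tolerance = 1e-9)
  r <- find_cutoff(cv, ab)
  expect_equal(r$cutoff_x, 20, tolerance = 1e-9)
})

test_that("no intersection fails loudly with a directional diagnostic", {
  ab <- hofstee_line(hofstee_params(35, 45, 6, 18))
  # everyone scores high: curve entirely to the right / below AB
  expect_error(find_cutoff(build_cumulative_curve(score_set(c(90, 95, 100))), ab),
               "below AB.*too few")
  # everyone scores low: curve entirely above AB in the window
  expect_error(find_cutoff(build_cumulative_curve(score_set(c(5, 10, 15))), ab),
               "above AB.*too many")
  # overlapping x-range but curve above AB throughout
  expect_error(find_cutoff(build_cumulative_curve(score_set(c(20, 30, 40))), ab),
               "above AB.*too many")
})

test_that("corner fallback substitutes the nearer AB endpoint in failure-rate distance", {
  ab <- hofstee_line(hofstee_params(35, 45, 6, 18))
  cv <- build_cumulative_curve(score_set(c(20, 30, 40)))  # curve above AB
  r <- find_cutoff(cv, ab, fallback = "corner")
  expect_true(r$fallback)
  expect_true(is.na(r$segment_index))
  # curve at 35 is ~66.7, at 45 is 100: endpoint A (35,18) is nearer in y
  expect_equal(unname(c(r$cutoff_x, r$cutoff_y)), c(35, 18))
  expect_match(r$diagnostic, "too many")
})

test_that("vertical AB crosses at c_min when the curve value lies within the f-range", {
  s <- score_set(c(5, 8, 12, 15, 18, 22, 26, 30, rep(40, 9),
                   seq(41, 97, length.out = 83)))
  cv <- build_cumulative_curve(s)
  ab <- hofstee_line(hofstee_params(38, 38, 5, 20))
  r <- find_cutoff(cv, ab)
  expect_equal(r$cutoff_x, 38, tolerance = 1e-9)
  expect_equal(r$cutoff_y, curve_value_at(cv, 38), tolerance = 1e-9)
  # f-window that excludes the curve value -> diagnostic
  expect_error(find_cutoff(cv, hofstee_line(hofstee_params(38, 38, 1, 3))),
               "no intersection")
})

test_that("algebraic scan agrees with the brute-force oracle on random configurations", {
  agree <- 0L
  for (seed in 1:60) {
    cfg <- random_config(seed)
    cv <- build_cumulative_curve(cfg$scores)
    ab <- hofstee_line(cfg$params)
    r <- try_cutoff(cv, ab)
    o <- brute_force_cutoff(cv, ab)
    expect_identical(is.null(r), is.null(o),
                     info = sprintf("existence mismatch at seed %d", seed))
    if (!is.null(r)) {
      expect_equal(r$cutoff_x, o, tolerance = 1e-6,
                   info = sprintf("location mismatch at seed %d", seed))
      agree <- agree + 1L
    }
  }
  expect_gt(agree, 10L)  # the configuration space must actually exercise crossings
})

test_that("cut-off is invariant to shuffling the raw scores", {
  # first seeded configuration whose curve actually crosses AB
  cfg <- NULL
  for (seed in 1:50) {
    cand <- random_config(seed)
    if (!is.null(try_cutoff(build_cumulative_curve(cand$scores),
                            hofstee_line(cand$params)))) { cfg <- cand; break }
  }
  ab <- hofstee_line(cfg$params)
  base <- find_cutoff(build_cumulative_curve(cfg$scores), ab)
  vals <- as.numeric(cfg$scores)
  for (seed in 1:5) {
    set.seed(seed)
    r <- find_cutoff(build_cumulative_curve(score_set(sample(vals))), ab)
    expect_identical(r$cutoff_x, base$cutoff_x)
    expect_identical(r$segment_index, base$segment_index)
  }
})

test_that("the crossing is unique when AB is strictly decreasing", {
  for (seed in 1:20) {
    cfg <- random_config(seed + 500)
    cv <- build_cumulative_curve(cfg$scores)
    ab <- hofstee_line(cfg$params)
    hits <- 0L
    for (i in seq_len(nrow(cv) - 1L)) {
      p <- intersect_segments(ab, line_segment(cv$x[i], cv$y[i],
                                               cv$x[i + 1L], cv$y[i + 1L]))
      if (!is.null(p)) hits <- hits + 1L
    }
    # a vertex-coincident crossing is shared by two adjacent segments
    expect_lte(hits, 2L)
    if (hits == 2L) {
      found <- which(vapply(seq_len(nrow(cv) - 1L), function(i)
        !is.null(intersect_segments(ab, line_segment(cv$x[i], cv$y[i],
                                                     cv$x[i + 1L], cv$y[i + 1L]))),
        logical(1L)))
      expect_equal(diff(found), 1L)
    }
  }
})

test_that("inserting a collinear vertex into a curve segment changes nothing", {
  cfg <- random_config(11)
  cv <- build_cumulative_curve(cfg$scores)
  ab <- hofstee_line(cfg$params)
  base <- find_cutoff(cv, ab)
  i <- base$segment_index
  mid_x <- (cv$x[i] + cv$x[i + 1L]) / 2
  mid_y <- curve_value_at(cv, mid_x)
  cv2 <- cv
  cv2 <- structure(rbind(cv[seq_len(i), ],
                         data.frame(x = mid_x, y = mid_y),
                         cv[(i + 1L):nrow(cv), ]),
                   n_students = attr(cv, "n_students"),
                   class = class(cv))
  r2 <- find_cutoff(cv2, ab)
  expect_equal(r2$cutoff_x, base$cutoff_x, tolerance = 1e-9)
  expect_equal(r2$cutoff_y, base$cutoff_y, tolerance = 1e-9)
})

test_that("translating scores and AB together translates the cut-off exactly", {
  delta <- 2.5
  s <- fig1_style_scores()
  ab <- hofstee_line(hofstee_params(35, 45, 6, 18))
  base <- find_cutoff(build_cumulative_curve(s), ab)
  s2 <- score_set(as.numeric(s) + delta)
  ab2 <- line_segment(ab[["x1"]] + delta, ab[["y1"]],
                      ab[["x2"]] + delta, ab[["y2"]])
  r2 <- find_cutoff(build_cumulative_curve(s2), ab2)
  expect_equal(r2$cutoff_x, base$cutoff_x + delta, tolerance = 1e-9)
  expect_equal(r2$cutoff_y, base$cutoff_y, tolerance = 1e-9)
})
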