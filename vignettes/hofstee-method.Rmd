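---
title: "The Hofstee compromise method: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Hofstee compromise method: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hofstee)
```

## The problem and the model

A pass/fail cut-off can be set absolutely (a criterion the cohort must
meet, regardless of how many fail) or relatively (a failure quota,
regardless of competence). Both extremes are hard to defend on their
own. The Hofstee method asks each judge for the region of acceptable
compromises instead: the lowest and highest score they would tolerate as
a pass mark (`c_min`, `c_max`) and the lowest and highest percentage of
students they would tolerate failing (`f_min`, `f_max`). All four are
percentages in [0, 100], with `c_min <= c_max` and `f_min <= f_max`
enforced per judge *and* after aggregation, with the error reporting
which level failed.

The compromise line AB joins A = (`c_min`, `f_max`) and
B = (`c_max`, `f_min`): moving along it trades a higher standard against
a lower failure rate. The cohort's cumulative percentage curve — the
percent of students scoring at or below each observed score — crosses AB
at exactly one point when the two meet at all (AB is strictly decreasing
where non-degenerate, the curve is non-decreasing). That crossing is the
cut-off: its x is the pass mark, its y the expected failure rate.

```{r example}
fit <- hofstee(c(5, 8, 12, 15, 18, 22, 26, 30, rep(40, 9),
                 seq(41, 97, length.out = 83)),
               params = c(35, 45, 6, 18))
fit
```

```{r chart, fig.width = 7, fig.height = 5}
plot(fit)
plot(fit, "detailed")
```

## The cumulative-curve convention

The load-bearing convention of the whole package is how the curve is
built: **one vertex per distinct score v at (v, 100·k/n)**, where k
counts students scoring at or below v, with straight segments between
consecutive vertices. Rank-based "at or below" percentages — not the
percentile-rank midpoint convention 100·(k − 0.5)/n, and not a smoothed
ogive. With 181 students whose 6th and 7th ascending scores are 53.5 and
54.5, the vertices are (53.5, 100·6/181) and (54.5, 100·7/181), i.e.
(53.5, 3.31) and (54.5, 3.87) at display rounding; the reference
calculators for this method print exactly these coordinates, which is
what pins the convention down. Duplicate scores collapse into a single
vertex carrying the full count, so the curve is strictly increasing in
both coordinates, and the last vertex is exactly (max score, 100).

No synthetic origin vertex is prepended: the curve starts at the lowest
observed score. A compromise below the minimum score is therefore
impossible by construction and is reported as a no-intersection
diagnostic rather than extrapolated.

## The intersection scan

The cut-off is found algebraically, never graphically: the curve's
segments are scanned in ascending x, each supporting line is intersected
with AB in closed form, and the first intersection satisfying the
x-range test `x1 <= xi <= x2` *and* lying on AB as a closed segment is
returned. The second condition is deliberately stronger than the bare
x-range test: an intersection beyond the ends of AB is not a compromise
the judges endorsed. Since at most one crossing exists, "first" is not a
tie-break but an optimisation; when the crossing lands exactly on a
shared vertex, both adjacent segments produce the identical point and
either is acceptable.

Numerical choices:

* All arithmetic is double precision; segment membership is tested with
  an absolute tolerance of 1e-9 so vertex-coincident crossings are not
  lost to rounding.
* Display values are rounded to 2 decimal places, half away from zero
  (37.615 → 37.62). Full precision is retained internally and in the
  JSON output.
* Vertical AB (`c_min == c_max`): the cut-off is `c_min` if the curve's
  value there lies within [`f_min`, `f_max`], otherwise a
  no-intersection diagnostic. Fully degenerate parameters (both pairs
  equal) are an error: AB is a point.
* Horizontal AB collinear with a flat curve stretch: the smallest-x
  point of the overlap is returned — the lowest passing standard
  consistent with the judgement.
* No intersection is an error by default, with a directional diagnostic
  (curve entirely above AB: more students fail than the judges accept;
  entirely below: fewer). `fallback = "corner"` opts into substituting
  the AB endpoint nearer to the curve in failure-rate distance; it is
  off by default because silently replacing a failed compromise with a
  box corner hides a disagreement the committee should see.

## Aggregating the judges

Arithmetic means are the method's standard aggregation; medians are
offered as the robust alternative, with the even-panel median taken as
the mean of the two middle values (the dominant convention). Standard
deviations use the sample (n − 1) form, treating the panel as a sample
of possible judges; a panel of one has SD 0 by definition. Because means
and medians preserve per-judge orderings, a validated panel can never
aggregate to an invalid parameter set. The library accepts any panel of
at least one judge; the CLI warns above ten, a practical rather than
methodological limit. No judge weighting, outlier exclusion or
inter-rater reliability beyond the SDs is attempted.

## Scores, files and the synthetic generator

Scores are percentages in [0, 100]; out-of-range values are an error,
never clipped, because a clipped score silently moves the curve and so
the cut-off. CSV reading takes the first column only, tolerates exactly
one leading header row, accepts point-decimal values, and sorts on read,
so row order never matters. Duplicates are kept — they shape the curve.

`generate_synthetic_scores(n, low, high, seed)` draws n integers
uniformly with replacement, emulating the spreadsheet-style
`RANDBETWEEN(low, high)` fixtures traditionally used to exercise the
method at scale (1,000 draws from [1, 100] being the customary stress
case). What it emulates is the *shape* of such fixtures — integer,
uniform, heavily tied; what it does not emulate is real exam data:
roughly bell-shaped, often left-skewed cohorts with half-point scores
and clumping near round numbers. Passing tests on uniform fixtures
therefore demonstrate the geometry and the bookkeeping, not
distributional robustness; the worked-example cohorts (with ties,
half-points and gaps) cover the realistic features the geometry must
survive.

## Gap report

Adjacent distinct scores with no student between them form a data gap;
a cut-off inside a wide gap separates the same students as any other
point of the gap, which committees like to know when defending a
standard. The report window defaults to [`c_min`, `c_max`] — the range
the detailed chart covers — because "the vicinity of the cut-off" is
otherwise unspecified; gaps are measured on the score axis, both
endpoints must lie inside the window, the widest `top_k` (default 3) are
reported, and ties break toward the lower score. The report is advisory
only; the cut-off is never adjusted automatically.

## Charts and pipeline

The full chart spans the data range; the detailed chart spans
[`c_min` − m, `c_max` + m] with m = 10% of `c_max` − `c_min`, a margin
chosen so the whole parameter box plus a visual buffer is in view.
Charts are a pure sink: rendering never feeds back into the numbers.
`run_pipeline()` (and the thin CLI over it) maps error classes to
distinct status codes — input 2, validation 3, no intersection 4 — and
writes no partial outputs on failure. JSON output is deterministic:
identical inputs give byte-identical documents.

## Problem sizes and verification

The test suite verifies the two published worked examples exactly at
display precision (37.62 and 53.80), pins the curve convention on a
181-score cohort, and runs a property suite on 500 seeded random
configurations (30–300 students each, random parameter boxes) comparing
the segment scan against an independent brute-force oracle: a 1e-4-step
sign-change scan refined by bisection, agreeing within 1e-6. Shuffle
invariance, crossing uniqueness, collinear-subdivision invariance and
translation equivariance are asserted on the same generated families.
These sizes keep the whole suite in the tens of seconds while covering
cohorts well beyond typical class sizes.

## Known limitations

* Only the segment-scan Hofstee compromise is implemented — no Beuk or
  Cohen methods, no closed-form frequency formulation, and no confidence
  interval on the cut-off (judge SDs are reported but not propagated).
* The curve is not extrapolated beyond the observed scores; cohorts
  whose scores all lie outside the parameter box yield a diagnostic, not
  a number.
* Scores are taken as final percentages; no rescaling, weighting or
  multi-cohort pooling.
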