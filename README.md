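# hofstee

Pass/fail cut-off scores for examinations with the Hofstee compromise
method, computed algebraically instead of read off a hand-drawn chart.

Standard setting in (medical) education needs a defensible pass mark.
Purely criterion-referenced standards ignore how the cohort actually
performed; purely norm-referenced standards fail a fixed fraction of
students regardless of competence. The Hofstee method is the classic
compromise: a panel of judges bounds the plausible cut-off score by
[c_min, c_max] and the tolerable failure rate by [f_min, f_max], and the
observed score distribution picks the compromise point inside that box.

This package is for exam committees, psychometricians and assessment
units who have a column of raw scores and a handful of judge judgements
and want the cut-off, its rationale and its chart in one reproducible
step.

## The method

1. Each judge j supplies (c_min, c_max, f_min, f_max), all percentages
   in [0, 100] with c_min ≤ c_max and f_min ≤ f_max.
2. The panel is aggregated per parameter by arithmetic mean (or median);
   sample standard deviations are reported alongside.
3. The cumulative percentage curve of the scores is built: one vertex per
   distinct score v at (v, 100·k/n), where k is the number of students
   scoring ≤ v, with straight segments between vertices.
4. The compromise line **AB** runs from A = (c_min, f_max) to
   B = (c_max, f_min). The cut-off is the intersection of AB with the
   cumulative polyline, found by scanning the curve's segments in
   ascending order and solving each line–line intersection exactly:
   for curve segment (x₁,y₁)–(x₂,y₂), the crossing x_i with AB is
   accepted when x₁ ≤ x_i ≤ x₂ and the point lies on AB as a closed
   segment.

Because AB is strictly decreasing while the cumulative curve is
non-decreasing, the crossing is unique when it exists. When it does not
exist (the curve passes entirely above or below the judges' box) the
package fails loudly with a directional diagnostic rather than invent a
number; an explicit corner fallback is available.

## Worked example

```r
library(hofstee)

# a 100-student cohort; judges bound the cut-off in [35, 45] and the
# failure rate in [6, 18]
scores <- c(5, 8, 12, 15, 18, 22, 26, 30, rep(40, 9),
            seq(41, 97, length.out = 83))
fit <- hofstee(scores, params = c(35, 45, 6, 18))
fit
#> Hofstee compromise standard (n = 100 students)
#>
#> Hofstee parameters (direct):
#>   cut-off score bounds  c_min = 35, c_max = 45
#>   failure-rate bounds   f_min = 6, f_max = 18
#>
#> Hofstee cut-off:
#>   cut-off score: 37.62 (full precision 37.61904762)
#>   expected failing: 14.86% of students
#>   crossing on cumulative segment #8
```

The cut-off 37.62 means: a pass mark of 37.62% is the point where the
judges' acceptable trade-off between standard and failure rate meets the
cohort's actual performance, and 14.86% of students fall below it.
`coef(fit)` returns the parameters and cut-off; `predict(fit, x)` gives
the cumulative percent at any score; `summary(fit)` adds the panel
statistics and the largest score gaps near the cut-off; `plot(fit)` and
`plot(fit, "detailed")` draw the full and zoomed Hofstee charts;
`hofstee_json(fit)` emits the machine-readable result.

With a judge panel instead of ready-made parameters:

```r
fit <- hofstee("scores.csv",
               judges = list(c(50, 60, 1, 4), c(44, 56, 3, 8),
                             c(41, 52, 4, 8), c(45, 54, 5, 8),
                             c(45, 53, 2, 7)),
               method = "mean")   # aggregates to (45, 55, 3, 7)
```

## Command line

```sh
Rscript inst/cli/hofstee.R --scores scores.csv --judge 50,60,1,4 --judge 44,56,3,8 \
    --method mean --chart both --out charts/ --json result.json
Rscript inst/cli/hofstee.R synth --n 1000 --low 1 --high 100 --seed 42 --out-file fixture.csv
```

Exit codes distinguish input errors (2), parameter validation errors (3)
and a missing intersection (4).

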