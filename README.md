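# cusumlc

CUSUM learning-curve analysis for procedural competency assessment.

`cusumlc` is for educators and researchers who monitor how trainees acquire a
manual clinical skill — the motivating case is novice anaesthesia trainees
learning lumbar epidural block — from sequences of binary attempt outcomes
(0 = success, 1 = failure). It builds the cumulative-failure control chart,
derives its decision boundaries from Wald's sequential probability ratio test
(SPRT), classifies each trainee by the first boundary crossing, and compares
cohorts (for example, trainees taught with a structured model versus a
standard one) on how many reach competence and how fast.

## The chart and its boundaries

The chart plots the cumulative failure count S(n) against the attempt number
n. Competence is framed as a sequential test between an acceptable failure
rate p0 and an unacceptable rate p1, with type I and type II error rates
alpha and beta. With natural logarithms,

    a = ln[(1 - beta)/alpha]        b = ln[(1 - alpha)/beta]
    P = ln(p1/p0)                   Q = ln[(1 - p0)/(1 - p1)]
    s = Q/(P + Q)

the two control lines share slope s (failures per attempt):

    h0(n) = s·n - b/(P + Q)    lower line: acceptable performance
    h1(n) = s·n + a/(P + Q)    upper line: unacceptable performance

A trainee is declared **competent** the first time S(n) <= h0(n),
**unacceptable** the first time S(n) >= h1(n), and **indeterminate** if
neither happens within the observed attempts. Touching a line counts as a
crossing; when both would trigger at the same attempt the lower line wins
(the convention favours the trainee), and the first crossing is terminal.

With the conventional setting p0 = 0.10, p1 = 0.30, alpha = beta = 0.10 the
slope is s = 0.1862 and an error-free trainee crosses the lower line at
exactly attempt 9.

Cohorts are compared with a crude odds ratio (Woolf log-OR confidence
interval, Haldane–Anscombe correction for zero cells), a logistic regression
of achievement on group fitted by iteratively reweighted least squares, and
a Welch t-test on the attempts needed to reach competence. A sensitivity
grid re-runs the whole comparison over alternative (p0, p1) settings. A
simulator with an exponential-decay learning model supports
operating-characteristic and power studies; see the methods vignette
(`vignettes/cusum-learning-curves.Rmd`) for the model and all defaults.

## Worked example

The package bundles a small synthetic cohort
(`inst/extdata/synthetic_example_cohort.csv`, 21 trainees per arm) whose
attempt patterns are engineered so that, at the primary (0.10, 0.30)
setting, 14 study and 8 control trainees achieve competence:

```r
library(cusumlc)
rec <- read_attempts(system.file("extdata", "synthetic_example_cohort.csv",
                                 package = "cusumlc"))
a <- run_analysis(rec)
print(a)
```

```
CUSUM learning-curve analysis
-----------------------------
Cohort comparison at p0 = 0.1, p1 = 0.3 (alpha = 0.1, beta = 0.1)
  achievers: study 14/21 (67%), control 8/21 (38%)
  crude OR 3.25 (95% CI 0.918-11.5), p = 0.0677
  logistic OR 3.25, p = 0.0677
  attempts to competence: study 13.5 (+/-4.5, n=14), control 12.6 (+/-4.2, n=8)
  Welch t = 0.459, df = 15.5, p = 0.653

Sensitivity to the failure-rate setting:
  p0   p1 study_yes study_pct control_yes control_pct   or ...
 0.1 0.30        14        67           8          38 3.25
 0.1 0.40        11        52           7          33 2.20
 ...
```

Reading the output: 67% of study trainees versus 38% of controls crossed the
lower (acceptable-performance) line, giving a crude odds ratio of
14·13/(7·8) = 3.25; the logistic fit reproduces it exactly, as it must for a
single binary covariate. The attempts-to-competence means are computed over
achievers only. The sensitivity rows show how the verdicts move as the
acceptable/unacceptable rates change; the fixture's deterministic patterns
are engineered for the primary setting, so other rows differ (at 0.20/0.30
no fixture trainee crosses within its short series and the odds ratio is
reported as undefined).

Per-trainee charts are available as tables or plots:

```r
k <- sprt_constants(failure_rates(0.10, 0.30))
s <- build_series(rec[rec$trainee_id == "S01", ])
chart_table(s, k)   # n, cum_failures, h0, h1
plot(s, k)          # step curve with both control lines
```

and simulated cohorts via `simulate_cohort(cohort_design(...))`,
`operating_characteristics()` and `simulate_power()`. A thin command-line
front end with `simulate` / `analyze` / `sensitivity` / `chart` subcommands
lives at `inst/scripts/cusum-cli.R`.

## Notes on published values

Two reporting quirks of the motivating study are surfaced rather than
hidden: its table reports 21 trainees per group while the enrolment text
says 22 (the package always takes group sizes from the data), and one
printed odds ratio (3.15) does not reproduce from its own printed counts
(which give 3.25). Printed confidence intervals match no standard
crude-OR method, so this package standardises on the Woolf interval.
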