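# dtainterim

Exact group sequential interim analysis for diagnostic test accuracy
(DTA) studies.

Prospective DTA studies estimate a test's sensitivity and specificity
against a reference standard in a single cohort.  When early data show
the test cannot plausibly reach a minimally acceptable accuracy,
stopping the study for futility saves participants, money and time.
`dtainterim` gives study statisticians the machinery for that: exact
group sequential futility boundaries for both co-primary endpoints,
interim scheduling by total participants or by disease-positive cases,
decision evaluation of accrued data, exact operating characteristics,
sample size re-estimation from observed prevalence, and a synthetic
cohort simulator for design calibration.

## The method

Because group sequential methods for a single proportion assume the
monitored proportion is below one half, each accuracy endpoint is
monitored on its complementary error rate — the false-negative rate
(FNR, 1 − sensitivity) or false-positive rate (FPR, 1 − specificity).
For an accuracy threshold `p0`, the threshold error proportion is
`p_t = 1 − p0` and the hypotheses are `H0: p ≤ p_t` vs `H1: p > p_t`;
rejecting `H0` is stopping for futility.  At an analysis with
cumulative endpoint-group size `n_g`, the study stops when the observed
failure count reaches

    r_g = floor( n_g·p_t + 0.5 + z_{1−α} · sqrt( n_G·p_t·(1−p_t) ) ) + 1,

where `n_G` is the planned final (anchor) group size.  Anchoring the
deviate term to `n_G` makes early stopping require stronger evidence
than the final analysis; on the accuracy scale the stage boundary is
`1 − r_g/n_g`, with estimates at or below it (equality included)
triggering stopping, and negative boundaries (`r_g > n_g`, stopping
impossible) shown as dashes.  The two endpoints each use a one-sided
per-endpoint `α` (default 0.05) and are combined by a futility rule —
by default the study stops when *either* endpoint crosses.  Exact
stagewise stopping probabilities, the attained type I error and the
expected sample size are computed by binomial convolution, with no
normal approximation.

## Worked example

A 200-participant study at an assumed prevalence of 35% requires 75%
sensitivity and 90% specificity, with interim analyses after 15, 25 and
50 disease-positive cases and a final analysis at 70 (so 130 expected
negatives):

```r
library(dtainterim)
design <- dta_design(prevalence = 0.35, schedule_by = "positives",
                     schedule_points = c(15, 25, 50), target = 70,
                     sens_p0 = 0.75, spec_p0 = 0.90)
print(boundary_set(design$sens_endpoint))
#> Futility boundaries (FNR endpoint, p0 = 75% sensitivity, one-sided alpha = 0.05, anchor n = 70)
#>  stage  n stop if failures >= accuracy boundary
#>      1 15                  11               27%
#>      2 25                  13               48%
#>      3 50                  19               62%
#>      4 70                  24               66%
```

Reading down the table: at the first interim the study stops only if at
least 11 of the first 15 positive cases are false negatives (observed
sensitivity ≤ 27%) — far below the 75% requirement, since only strong
early evidence should terminate a study — while by the final analysis
the bar has risen to 66%, just under `p0`.  The attained type I error
of this boundary set is exact, not nominal:

```r
exact_type_I_error(boundary_set(design$sens_endpoint))
#> attained type I error: 0.0613
```

Monitoring one of the shipped example cohorts (a mediocre test: true
sensitivity 65%, specificity 85%, prevalence 35%):

```r
cohort <- read_participants(system.file("extdata", "sim_cohort1.csv",
                                        package = "dtainterim"))
monitor_dta(design, cohort)
#>  N (N_pos) Sensitivity (boundary) Specificity (boundary) Sensitivity decision
#>    46 (15)              67% (27%)              81% (68%)             Continue
#>    63 (25)              60% (48%)              84% (74%)             Continue
#>   128 (50)              56% (62%)              82% (82%)    Stop for futility
#>  Specificity decision          Decision
#>              Continue          Continue
#>              Continue          Continue
#>     Stop for futility Stop for futility
```

The 15th positive case arrives with participant 46, so the first row
evaluates 15 positives and 31 negatives.  At the third interim the
observed sensitivity (56%) has fallen to the boundary region and the
specificity estimate (82%) sits exactly on its boundary — equality
stops — so the study terminates for futility after 128 of the planned
200 participants.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "dta-interim.R", package = "dtainterim")`, with
`design`, `monitor` and `simulate` subcommands (monitor exits 0 to
continue, 3 on a stop, for pipeline use).  The YAML design schema is
documented in `?read_design`; this example's configuration is:

```yaml
prevalence: 0.35
schedule:
  by: positives
  points: [15, 25, 50]
  target: 70
sensitivity: {p0: 0.75}
specificity: {p0: 0.90}
alpha: 0.05
futility_rule: either
```

The package also ships a second simulated cohort and two synthetic
point-of-care test cohorts (`raptor_*_synthetic.csv`, reconstructed
accrual for a SARS-CoV-2 case study evaluated against regulatory
target product profiles) used by the test suite; see
`vignettes/interim-monitoring.Rmd` for the model, the design decisions
and the simulator's scope.

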