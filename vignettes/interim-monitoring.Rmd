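---
title: "Exact group sequential interim monitoring of diagnostic accuracy studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact group sequential interim monitoring of diagnostic accuracy studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtainterim)
```

## The monitoring problem

A prospective diagnostic test accuracy (DTA) study recruits a single
cohort, applies the index test and a reference standard to every
participant, and summarises performance as a pair of proportions:
sensitivity (the true positive rate, estimated among disease-positive
participants) and specificity (the true negative rate, among
disease-negative participants).  When a test is unlikely to reach a
minimally acceptable accuracy, continuing to the planned sample size
wastes resources and delays the evaluation of better candidates.
Interim analyses with a futility stopping rule address this: at a small
number of pre-specified accrual points the accumulating data are
compared against stopping boundaries, and the study terminates early if
the evidence of inadequate accuracy is already strong.

`dtainterim` implements an adaptation of the exact group sequential
method for binomial endpoints to this bivariate setting.  Because the
method assumes the monitored proportion is below one half, and
acceptable sensitivities and specificities are well above it, each
endpoint is monitored on its complementary error rate: the
false-negative rate $p = 1 - \text{sensitivity}$ (FNR) or the
false-positive rate $1 - \text{specificity}$ (FPR).  For an accuracy
threshold $p_0$ (say, 75% sensitivity), the threshold error proportion
is $p_t = 1 - p_0$ and the hypotheses are

$$H_0\colon p \le p_t \qquad \text{vs.} \qquad H_1\colon p > p_t,$$

with rejection of $H_0$ corresponding to stopping for futility.  The
package warns, rather than fails, if a design implies $p_t \ge 0.5$ or
more than five analyses in total, since both are violations of
recommendations rather than of the arithmetic.

## The boundary construction

Let $n_g$ be the cumulative endpoint-group size at analysis
$g = 1, \dots, G$ and $n_G$ the planned final (anchor) size.  The
futility boundary at stage $g$ is a failure count

$$r_g = \left\lfloor n_g\,p_t + 0.5 + z_{1-\alpha}
  \sqrt{n_G\, p_t (1 - p_t)} \right\rfloor + 1,$$

and the stage stops the study when the observed number of failures
(false negatives or false positives) reaches $r_g$.  Equivalently, on
the accuracy scale the stage boundary is $1 - r_g/n_g$, and an
estimate *at or below* the boundary stops: equality stops, and all
decisions are taken on integer counts, never on rounded percentages.
Two features matter:

* **Final anchoring.** The normal-deviate term uses $n_G$, not $n_g$.
  Early analyses therefore demand a stronger level of evidence than the
  final one — on the accuracy scale every attainable interim boundary
  sits strictly below $p_0$, approaching it as accrual nears the
  anchor.  This is what keeps the overall type I error close to the
  per-analysis $\alpha$ without an explicit spending function.
* **Unattainable stages.** At small $n_g$ the count $r_g$ can exceed
  $n_g$: stopping is impossible even if every observation is a failure.
  Such boundaries are negative on the accuracy scale and are displayed
  as dashes.

The construction is approximate in the sense that the attained type I
error is not re-solved to hit $\alpha$ exactly; boundaries are fixed by
the formula for any planned sample size.  Instead the package exposes
the exact operating characteristics: `stagewise_probabilities()`
propagates the cumulative failure-count distribution by binomial
convolution (masses from `dbinom()`, which is numerically stable;
probability conservation is asserted to within $10^{-12}$),
`exact_type_I_error()` evaluates the total rejection probability at
$p = p_t$ (the supremum over $H_0$, by monotonicity in $p$), and
`expected_sample_size()` quantifies the efficiency gain.  For the
worked 70-positive sensitivity design below the attained level is about
0.061 at a nominal $\alpha = 0.05$ — slightly anticonservative, which
users should check at design time with these functions.

```{r}
ep <- endpoint_design("FNR", p0 = 0.75, alpha = 0.05,
                      stage_sizes = c(15, 25, 50), anchor_size = 70)
boundary_set(ep)
exact_type_I_error(boundary_set(ep))
```

### Efficacy boundaries

An acceptance (efficacy) boundary mirrors the construction with an
alternative error rate $p_a < p_t$ and deviate $z_{1-\beta}$
subtracted:
$a_g = \lceil n_g p_a - 0.5 - z_{1-\beta}\sqrt{n_G p_a (1-p_a)}
\rceil - 1$, capped at $r_g - 1$, with the final stage forced to
$a_G = r_G - 1$ so the final analysis always terminates.  The mirror
form was a genuine design choice: no worked example pins it down, so it
is validated against a brute-force path-enumeration oracle in the test
suite rather than against published numbers.  Efficacy stopping is
**disabled by default** — in a DTA study every participant receives the
test, so continuing to the target rarely disadvantages anyone and buys
precision; stopping early "for success" is seldom appropriate.

## The bivariate design

`dta_design()` couples an FNR and an FPR endpoint with an accrual
schedule.  Interims may be scheduled by total participants or by
disease-positive cases; the assumed prevalence $\pi$ converts schedule
points into planned per-endpoint group sizes (positives
$\approx N\pi$, negatives $\approx N(1-\pi)$, or negatives
$\approx N_{pos}(1-\pi)/\pi$ under a by-positives schedule).
Projections use round-half-away-from-zero; the worked anchors are
integer-exact so the choice is documented for reproducibility only.

Three scheduling decisions were open and are resolved as follows:

* **Observed sizes, planned anchor.** At analysis time the observed
  group sizes replace the projections (under a by-positives schedule
  the specificity group is simply however many negatives have accrued),
  but boundaries keep the planned anchor $n_G$ — even when accrual
  overshoots it.  This keeps the pre-specified boundary scale fixed.
* **Overshoot retention.** An analysis uses all data available when its
  milestone is crossed.  With participant-level data the cut is the
  first record reaching the milestone; when records carry a `day`
  column (data arriving in batches), the cut is the first end-of-batch
  position at or beyond it, so an interim "after 50 cases" may well
  include 52.
* **Same-cut evaluation.** Both endpoints are evaluated on the same
  participant cut, so each report row has a single $N$.

The default futility combination is `"either"`: a test required to meet
minimum levels on both measures fails as soon as either endpoint
crosses its boundary.  The alternative `"both"` rule is stricter about
stopping (its stop set is a subset of either's, a property the tests
check).  Efficacy, when enabled, always requires both endpoints.  An
endpoint with an empty group (no positives accrued yet, say) is
reported `"Not evaluable"` and never contributes to stopping — a
conservative choice.  After an overall stop, later scheduled analyses
are not evaluated: the study is terminated.

Interim prevalence checks are supported by `reestimate_target()`, which
preserves the originally required number of positives under the
observed prevalence (e.g. 70 required positives at an observed
prevalence of 0.25 re-target 280 participants); the integer ceiling is
guarded against floating-point error so that an unchanged prevalence is
an exact identity.

## Display conventions

Boundary and estimate percentages are displayed with
round-half-to-even (base R `round()`), at 0 or 1 decimal places;
negative boundaries render as dashes.  Half-even is deliberate: the
worked boundary $1 - 7/8 = 12.5\%$ displays as 12%, which
half-away-from-zero would miss.  Rendering never feeds back into
decisions, which are made upstream on counts; the lossless CSV writer
(`write_monitor_csv()`, 17 significant digits) round-trips results
exactly.

## The cohort simulator

`simulate_cohort()` draws independent participants in recruitment
order: disease status Bernoulli($\pi$), then the index test result
Bernoulli(sensitivity) among the diseased and
Bernoulli($1-$specificity) among the non-diseased.  The shipped
example cohorts follow the same scenario as the package's simulated
worked example: sensitivity 65%, specificity 85%, prevalence 35%, a
mediocre test against thresholds of 75% and 90%.  `simulate_oc()`
estimates operating characteristics by Monte Carlo, with one sub-seed
per replicate spawned from a root seed so summaries are bit-reproducible
and single replicates can be regenerated in isolation.

The generator emulates the statistical structure a single-cohort DTA
study needs for boundary evaluation — binomial counts accruing in
sequence — and nothing else.  Real data features it does **not**
produce include prevalence drift over calendar time, accuracy varying
with disease severity or patient covariates (spectrum effects),
imperfect or delayed reference standards, and correlation between
repeat tests.  Passing simulation-based tests therefore demonstrates
that the boundary arithmetic and its operating characteristics are
correct under the stated model, not that the model captures any
particular real study.

## Numerical validation choices

The test suite validates the probability recursion against an
independent oracle that enumerates every ordered failure sequence, for
designs with up to 12 final-stage observations and three stages (the
enumeration is exponential, and this range already exercises
convolution, harvesting and both boundary types; agreement is required
to $10^{-10}$).  The Monte Carlo cross-check runs the full monitoring
pipeline on 50{,}000 replicate cohorts of 350 participants at the
sensitivity threshold $p_t = 0.25$ with perfect specificity, and
requires the empirical futility frequency to sit within three Monte
Carlo standard errors of the exact recursion; cohort size 350 makes the
probability of a replicate failing to reach the 70-positive anchor
negligible ($\approx 10^{-8}$).  Simulator fidelity is checked on a
100{,}000-participant cohort against three binomial standard errors.

## Known limitations

* The attained type I error is approximate (slightly above nominal for
  the worked designs); boundaries are not re-solved to hit $\alpha$
  exactly, and the two endpoints are monitored independently with no
  multiplicity adjustment across them and no joint (bivariate)
  modelling of the error rates.
* Estimates from a study stopped early are biased and the package makes
  no bias correction; interim estimates carry no confidence intervals.
* Continuous (per-participant) monitoring via alpha-spending, ROC/AUC
  endpoints, imperfect-reference adjustments and multi-test
  drop-the-loser designs are out of scope.
* The efficacy construction, while internally validated, has no
  external worked example; treat it as a sensible mirror of the
  futility rule rather than an established convention.
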