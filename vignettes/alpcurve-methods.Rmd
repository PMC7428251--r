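---
title: "Modelling transhumant lactation curves: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transhumant lactation curves: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpcurve)
```

This vignette explains the statistical model behind `alpcurve`, the
reasoning behind its defaults, and the design decisions taken where more
than one defensible choice existed. It states no empirical result that the
package's tests do not themselves compute.

## The problem

Dairy cows in alpine regions are summered on high mountain pastures for
roughly a hundred days ("alping"). Feed deficit and climatic stress on the
alp cause a drop in milk yield that is much steeper than the gentle
post-peak decline assumed by standard lactation models, followed by a
short production boost when the cow returns to the lowland farm. Official
milk recording delivers only about one test-day record per cow per month,
so per-cow curve fitting is hopeless for a six-parameter shape: the
fitting unit here is the *calving-month cohort*, whose records are
averaged per day in milk (DIM) into a smooth daily curve.

## The model

For DIM `t`, cohort ascent/return DIMs `t1 < t2`:

$$Y(t) = a + b\,e^{-kt} + c\,t + d\,\max(0, t-t_1)
       + f\,\min\!\big(1, \max(0, \lceil (t-t_2)/305 \rceil)\big)
       + g\,\max(0, t-t_2)$$

* `a` (kg) anchors the lactation level; `b` (kg, negative) scales the
  early exponential rise; `c` (kg/day) is the ordinary post-peak decline.
* `d` (kg/day) is the *additional* slope while the cow is alped: the total
  decline on the alp is `c + d`. The milk lost over `x` alped days is
  approximately `|d| x^2/2` (`milk_loss()`), the integral of the extra
  decline.
* `f` (kg) is a 0/1 step: the instantaneous boost after return.
* `g` (kg/day) is the additional post-alping slope (total post-alping
  decline `c + d + g`; the `d` hinge keeps accumulating, which is what
  makes the boost-plus-steeper-tail shape expressible with one linear
  model).

`k` is fixed at 0.1/day, the conventional value that keeps the model
linear in its parameters; `estimate_k()` exists purely as a validation
utility (profile search with inner weighted least squares) and is not used
in reported fits. The model is fitted by weighted least squares with the
per-DIM observation counts as weights, via `lm()`.

**The boost indicator.** The ceiling expression is read as a clamped 0/1
indicator of `t > t2`: it turns on the day after return and the clamp
keeps it binary (rather than 2) beyond `t2 + 305`. `integrate_production()`
uses the same reading, so model and closed-form integral agree exactly;
the model is intended for standard lactations, and within the package's
500-DIM horizon the distinction beyond `t2 + 305` never arises.

**Log-likelihood convention.** G-statistics are computed as
`2 (ll_alt − ll_null)` with the weighted Gaussian log-likelihood at the
MLE variance (what `logLik.lm` returns), with the *same* weight vector in
both models. This makes nested comparisons internally consistent and
reproduces `lmtest::lrtest()` exactly (checked in the test suite).

## Locating the transitions

The cohort's ascent and return DIMs must be estimated from the records.
Three estimators are provided (`locate_transitions()`):

* `"midpoint"` (default): per lactation, the true ascent day lies in the
  integer interval between the last pre-alp record and the first alp
  record, and the return day between the last alp record and the next
  record; the estimator takes the centre of that interval (with the
  half-day shift the half-open interval implies on the ascent side) and
  the cohort median. Lactations whose records begin on the alp, or end
  there because of dry-off, carry no information about the herd's move
  and are excluded from the respective median.
* `"observed"`: the plain median of first/last alp-record DIMs. Under
  ~30-day sampling the first alp record falls on average half an interval
  *after* the true ascent, so this estimator is biased late by ~15 days;
  it is retained because it is the most literal reading of the records.
* `"calendar"`: derive the DIMs from a fixed calendar season
  (15 May – 31 Aug) and the calving dates, ignoring the records.

Because the boost is a 0/1 step, even a half-day error in `t2` leaks into
`f` (a shift δ of the hinge is absorbed as `g·δ` of boost height). For
final fits, `refine_transitions()` therefore profiles the weighted SSE of
the full model over a grid of knots around the record-based estimate — a
standard changepoint refinement. `t2` is profiled on whole days: for a
daily-resolved curve the design only changes at integers, and within a
unit cell the `f`/`g` trade-off makes the SSE exactly invariant, so whole
days are the natural identifiable parameterisation.

## Quality control

`apply_qc()` implements a fourteen-rule cascade (date-window trim,
insemination-interval, age-at-first-calving, breed and parental breed,
lactation length, calving interval, alp altitude band 1100–2600 m,
calving-month exclusion March–August, parity cap 9, first-record DIM cap
42, pre-calving records, DIM window 5–500, second-alping-season trim) with
sequential accounting: an entity violating several rules is counted at the
first, and cow- or lactation-level removals cascade downwards so that at
every level input = survivors + removals.

Two evaluation details keep the cascade *idempotent* (a fixpoint — rerun
on its own output it removes nothing): the lactation-length and
first-record rules are evaluated on the records that survive the
record-level DIM window and second-run trim. Otherwise a record removed by
the later record-level rules could drop a lactation's observed span below
threshold only on a second pass. Ages are compared in exact days against
2 × 365.25 and 4 × 365.25, since the thresholds are stated in years. The
insemination-interval rule averages the per-lactation first-to-last
insemination spans over the first up-to-three lactations that have any
insemination recorded; cows with none recorded are not evaluable and are
kept.

The second-alping rule removes only the records of the second (and later)
maximal run of alp records — the final part of the curve — not the
lactation.

## Climate exposure

Daily THI (heat load: maximum temperature + relative humidity) and CSI
(cold load: mean temperature, wind, rain) are computed at each alp from
gridded temperature/rain (nearest cell, no bilinear smoothing — only
station variables are interpolated) and station RH/wind (squared
inverse-distance weighting within 50 km; a record with no station in range
gets a missing exposure). Grid temperatures are lapse-corrected to the alp
altitude with a single configurable gradient, −0.45 °C/100 m for both
maximum and mean temperature; RH and wind are not elevation-corrected.
Exposures are averaged over the 3 or 30 calendar days *strictly before*
the record date — the record day is excluded, the conservative reading of
a "before the record" window. A missing day anywhere in the window makes
the exposure missing; such records drop out of climate contrasts but still
enter curve fitting, since exposure is only used for grouping.

## Factor contrasts

A factor splits a calving-month cohort into two contrasted groups — bottom
vs top tertile, or middle vs top for THI and CSI (production is best under
mild conditions, so the coldest/hottest thirds are contrasted against the
middle). Tertile cutoffs and membership are computed *within the cohort
being contrasted*: cutoffs pooled across calving months can leave one
group empty in a single month whenever the factor correlates with calving
date (pregnancy stage at ascent is the clearest case). Values exactly on a
cutoff are excluded from both groups.

Membership is per-record for the climate indices (the exposure at that
test day) and per-lactation for everything else. Environmental factors act
only during the alp stay: the curve is modelled only to `t2` (`f`, `g` not
estimated) and only `d` carries a group interaction; for the record-level
climate factors both groups share the pre-alping lowland baseline.
Physiological and morphological factors act over the whole cycle: all six
parameters carry interactions. The null model drops all interactions;
`G = 2(ll_alt − ll_null)` is referred to a chi-square with one df per
interaction and Bonferroni-corrected with a family size `m` supplied by
the caller (conventionally factors × months; the family is an analysis
choice, which is why `bonferroni()` takes `m` explicitly rather than
inferring it).

The reference group is the one producing more during alping
(`[t1, t2]` integral of the fitted group curve); percent differences are
`(other − ref)/ref × 100` and `Δd = d_ref − d_other`, positive when the
reference group is less impacted by alping. Pregnancy stage at ascent
calls conception as the insemination that precedes the next calving by
270–290 days when a next calving is known, else the last insemination.

For cross-month comparisons of the alping impact the per-month fits
up-weight the pre-alping points by ×100 — the loss approximation requires
the early curve to be fitted tightly — and restrict to first lactations,
because parity and calving month are confounded in such data. Both are
config switches in `run_pipeline()`.

## The synthetic herd generator

`simulate_herd()` emulates the statistical structure the analysis assumes,
with known ground truth:

* **Recording** as monthly herd visits: each cow gets a visit-schedule
  offset uniform over the ~30-day interval, independent of her calving
  date, with 30 ± 3-day gaps; the first visit at DIM ≥ 5 becomes the first
  record (it lands by DIM ~35, within the regulatory 5–42 window). The
  phase-uniformity of a calendar visit schedule matters: drawing the first
  record DIM uniformly instead skews the sampling phase and biases
  record-based transition estimates by a couple of days.
* **Calendar**: everyone ascends on 15 May and returns on 31 August.
  Calvings default to the 15th of the month, so a calving-month cohort
  shares its transition DIMs (up to the odd leap-year day across calving
  years) and the cohort-level hinge model is exactly the generating model;
  `calving_day_jitter` spreads calving days to emulate the real-data
  smearing of the hinge.
* **Yields** from the model family with per-cow Gaussian deviations on `a`
  and `d`, residual noise, and a floor at zero. The default seasonal
  pattern grades `d` from −0.08 kg/day (September calving, alped at the
  end of the cycle) to −0.02 (February calving, alped mid-cycle), the
  pattern these herds show; a single-`d` truth is a config switch.
* **Dry-off** ends recording where the cohort-level noiseless curve falls
  below `dry_off_kg` (default 3 kg — by the end of an alped lactation
  these extensively farmed cows are milked down to a few kg/day), plus a
  cow-level jitter drawn independently of the cow's yield. That
  independence is deliberate: if cows left the data when *their own* curve
  ran out, late-lactation cohort means would be survivor-selected upwards
  and no averaging estimator could be expected to recover the generating
  parameters. The default between-cow spread is likewise kept small
  (sd 1.5 kg on `a`, 0.003 kg/day on `d`) so cow-level curves stay
  positive over the recorded span and the zero floor stays inactive;
  larger spreads are available and push the cohort tail into floor
  censoring, which the averaged-curve estimator (correctly) cannot undo.
* **Climate** as smooth deterministic fields of position, elevation and
  day-of-year with a planted lapse structure, gridded at 2 km with a
  smooth reference elevation surface, and noisy stations sampling the
  RH/wind fields.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: heteroscedastic and non-Gaussian measurement
error, herd/management effects and concentrate feeding, genetic trends,
seasonal feed quality, yield-dependent culling and dry-off (the survivor
selection just described), irregular recording schemes, and weather that
deviates from a smooth field. Recovery results on this generator validate
the *estimator machinery*, not the biological completeness of the model.

`simulate_violations()` plants entities that each violate exactly one
quality-control rule on top of a clean herd, so the cascade's per-rule
accounting can be checked against ground truth.

## Numerical choices and degenerate inputs

* Weighted least squares via `lm()` on named design columns; singular
  designs (e.g. no post-alping points) fail early, naming the collinear
  columns.
* Knot profiling uses a full 2-D grid (half-days for `t1`, whole days for
  `t2`, ±8 days) rather than coordinate descent, which can stall one day
  off when `f` compensates a wrong `t2`.
* `estimate_k()`: coarse grid on [0.01, 0.5], golden-section refinement in
  the best cell; a flat profile or `|b|` below 1e−6 yields a warning and
  the conventional 0.1.
* Tertile cutoffs are type-7 quantiles; fewer than three distinct values,
  or an empty group, raise a typed `contrast-infeasible` condition that
  the pipeline logs and skips.
* IDW returns a station's exact value at zero distance; interpolated
  values are convex combinations, hence within the station range.
* All generator randomness flows from one seed; pipeline reruns with the
  same configuration are byte-identical.

## Test problem sizes

The suite validates parameter recovery on one simulated September cohort
of 10 000 cows from a single calving year (a recovery experiment fixes
the calendar so the cohort's transition days are unique; spreading calvings
over years only smears the knots by the leap-year day), contrast recovery
on 4 000 cows in two groups, and the G-test's type-I error on 500 null
simulations of 400 cows each — sizes at which the checked tolerances
(3 standard errors; empirical rejection in [0.03, 0.07]) are meaningful
for a suite that runs in a couple of minutes.

## Known limitations

* The model is piecewise-linear after the peak; real winter-calving curves
  bend non-linearly around the alping window, and the averaged fit cannot
  capture that.
* Averaging across cows dilutes individual effects; effect sizes from
  cohort curves are conservative.
* `t1`/`t2` are cohort constants; cows moving weeks apart within a cohort
  smear the hinges, biasing `d`, `f` and `g` slightly toward zero.
* A herd effect is not estimable from this data structure (hundreds of
  farms map onto hundreds of alps with no usable grouping), and none is
  attempted.
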