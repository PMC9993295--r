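---
title: "Allometric weight-band dosing: model, construction and comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allometric weight-band dosing: model, construction and comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allodose)
```

## The scaling model

`allodose` rests on a single closed-form model: a biological quantity
`Y` relates to body weight by the power law `Y = α · BW^b`.  For
clearance-type (metabolic) quantities the exponent is 0.75, and since
the steady-state maintenance dose is proportional to clearance, the
paediatric dose follows

```
Dose_child = Dose_adult × (W_child / W_ref)^0.75
```

`scaling_model()` carries the three parameters:

* `adult_value` — the adult dose in mg (600 for the ABC component of
  the ABC/3TC fixed-dose combination, whose 3TC component follows at
  half the ABC dose from the 2:1 tablet ratio).
* `reference_weight_kg` — the adult anchor, 70 kg by convention.  The
  model returns `adult_value` exactly at this weight.
* `exponent` — 0.75 by default; constrained to (0, 2].  Setting it to 1
  recovers linear mg/kg scaling, which is useful both as a numerical
  check and to quantify how much the two conventions disagree.

The model assumes a single power law over the whole weight range: no
maturation function, no body-surface-area term, and no drug-specific
exposure target.  It answers "what dose preserves adult-equivalent
clearance-scaled exposure", not "what exposure results" — the package
deliberately contains no pharmacokinetic simulation.

## From model to weight bands

Solid oral formulations quantise dosing: the 120/60 mg dispersible
tablet supports half-tablet increments, so the dispensable ABC doses are
120, 180, 240, 300, 360 mg, topped by the 600/300 mg adult tablet
(`abc3tc_formulary()`).  One printed source of the step list shows
"150 mg" for the 1.5-tablet entry; 1.5 × 120 mg is 180 mg, so the
packaged formulary treats that figure as a typographical slip and uses
180 mg.

Two rounding conventions connect continuous doses to these steps, and
both are first-class `rounding_policy()` modes because they serve
different purposes:

* **Per-patient conversion** uses `nearest`: the closest step to the
  exact allometric dose.  Exact midpoints (e.g. 150 mg between 120 and
  180) break to the *lower* step — conservative dosing; the choice is
  overridable via `tie_rule`.
* **Band construction** uses `ceil` implicitly: `weight_for_dose()`
  inverts the dose equation at each step `d`, giving the heaviest child
  for whom `d` is not an underdose; that weight becomes the band's
  upper edge, so every child in a band receives at least their exact
  allometric dose (to within edge rounding, see below).

Doses are capped at the adult dose by default (`cap_at_adult`): the
power law would otherwise extrapolate above it for weights beyond the
reference weight, which is never intended clinically.

`build_allometric_bands()` rounds each inverted edge to the table
resolution (0.1 kg, the granularity of clinical weight recording) and
starts the next band one resolution step higher.  Upper edges are
inclusive.  With the default inputs the finite edges are 8.2, 14.1,
20.6, 27.8 and 35.4 kg, and the adult band starts at 35.5 kg.  Printed
renderings of such tables are not always consistent about whether a
boundary weight belongs to the lower or upper band; this package fixes
the convention (inclusive upper edge) and applies it uniformly in
`lookup_dose()`.

Two numerical details make lookup total and stable:

* Weights are quantised half-up to the resolution before banding, with
  a 1e-9 relative epsilon so that a recorded 14.15 kg — stored by
  floating point as 14.1499… — still rounds up to 14.2 and lands in the
  higher band.  This also removes any dead zone between an upper edge
  and the next lower edge.
* Weights below the first band's lower edge (possible with the WHO
  chart, which starts at 3 kg) are assigned the first band and flagged
  `below_minimum` rather than erroring: the comparison stage must be
  total over any plausible cohort.  The packaged WHO chart's adult band
  is stored as unbounded above, since every child at or above 25 kg
  receives the adult tablet.

## The synthetic cohort generator

Individual patient records behind published demographic tables are
rarely deposited; what is published is per-age counts, mean weights and
weight ranges.  `default_cohort_spec()` encodes such a summary — 11 age
strata (2–12 years), n = 89, with a 40/89 male fraction — and
`generate_cohort()` draws synthetic patients from it:

* Within a stratum, weights follow a normal distribution truncated to
  the printed `[min, max]`, with `sd = range/4` so the printed extremes
  sit near ±2 standard deviations.  The range is the only dispersion
  information published, so any within-stratum distribution is a
  stand-in; this one is stated and overridable per stratum.
* The location parameter is *calibrated* (by root-finding) so that the
  truncated distribution's mean equals the printed stratum mean.  This
  matters: for strongly skewed ranges (mean 31.9 kg in 23.7–58.8 kg) an
  uncalibrated truncated normal centred on the printed mean would have
  its mean displaced upward by 2.7 kg, and the generated cohort would
  systematically overshoot the published summary.  The root-finder
  substitutes the analytic limits when the normal tail ratio
  degenerates numerically far from the bounds.
* Draws use inverse-CDF sampling, weights are rounded to 0.1 kg and
  clamped to the stratum range, and the whole cohort is a pure function
  of `(spec, seed)`; the caller's RNG state is restored afterwards.

What the generator does *not* emulate: within-stratum skewness (real
weight-for-age distributions have a heavy right tail), between-visit
measurement error, any sex–weight association, and secular growth.  One
consequence is visible in the package's own calibration tests: because
truncation shrinks the effective within-stratum standard deviation
below `range/4`, synthetic cohorts have *less* within-age dispersion
than a real clinic population, and their age–weight Pearson correlation
concentrates slightly higher than a comparable real cohort would show.
Passing generator tests therefore demonstrate internal consistency with
the published summary, not distributional fidelity to real records.

## The comparison stage

`run_comparison()` assigns every patient a dose under each strategy
(`band_strategy()` for table lookup, `allometric_strategy()` for
scale-then-round), tabulates the dose distributions, and reports:

* Mean ± SD of tablet counts per strategy.  Counts are the assigned
  dose divided by the 120 mg unit tablet, so the adult 600 mg tablet
  scores 5.0 unit-equivalents — the only mg-proportional way to put the
  adult tablet on the same scale as fractional paediatric counts.  An
  mg-scale comparison is available via `scale = "mg"`.
* The fraction of patients on the adult dose, per strategy.
* A two-sided Mann–Whitney rank-sum test between the first two
  strategies, on tablet counts.
* The Pearson age–weight correlation of the cohort (with r²).

The rank-sum test is implemented in the package rather than delegated,
because its two regimes need to be explicit.  The statistic `U` comes
from midranks (ties averaged).  For small groups — `min(n) ≤ 10` and at
most 2·10^5 subsets — the exact permutation distribution is enumerated
and `p = min(1, 2·min(P(U ≤ u), P(U ≥ u)))`.  Otherwise a normal
approximation with tie-corrected variance and 0.5 continuity correction
is used; it reproduces `stats::wilcox.test(exact = FALSE, correct =
TRUE)` to machine precision, which serves as an independent cross-check
in the test suite.  Degenerate input (all pooled values identical, zero
rank variance) returns p = 1 with a warning instead of dividing by
zero.  A known limitation, measured by the package's own tests: with
heavy ties and groups of 8 or fewer the normal approximation can miss
the exact p by several tenths — at those sizes the exact mode is the
only trustworthy one, which is why `method = "auto"` prefers it.

Cohorts of one patient produce a report with the test skipped (warning)
rather than an error; correlations require at least 3 patients and
non-zero variance on both axes.

## Problem sizes in the test suite

The suite's stochastic checks use sizes chosen to keep the whole run
within a few seconds while leaving no realistic sampling slack:
1 000 random doses for the round-trip and rounding brute-force checks,
10 000 random weights for band coverage, 200 random tied samples
(groups of 2–8) for the rank-sum enumeration comparison, 200 seeds of a
×10-scaled cohort (n = 890) for stratum-mean recovery and 100 seeds for
the correlation window and the strategy-dominance property.

## Known limitations

* The 0.75 exponent is asserted, not estimated; drugs with maturation-
  dependent clearance in the youngest children will not follow it.
* Band edges inherit the 0.1 kg rounding: at an edge the assigned step
  can fall short of the exact allometric dose by up to the local step
  spacing (checked as a property in the tests), which is the price of a
  printable table.
* The synthetic generator reproduces published summaries, not patients;
  conclusions about real cohorts should treat it as a plausibility
  harness only.
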