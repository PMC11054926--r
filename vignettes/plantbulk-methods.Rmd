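---
title: "Modeling nutrient adequacy of energy-scaled plant-based diets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nutrient adequacy of energy-scaled plant-based diets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantbulk)
```

## The question the model answers

Bodybuilders in an off-season ("bulking") phase eat far above maintenance to
maximize muscle accrual, and plant-based diets are widely assumed to need
careful planning to cover protein, leucine and micronutrients at that scale.
`plantbulk` formalizes a simple counter-argument: take the *nutrient density*
of an ordinary completely plant-based diet (nutrients per 2000 kcal, as
reported for the strict-vegetarian stratum of a large cohort), scale it
proportionally to the energy a bulking male bodybuilder actually needs, and
check every nutrient against its dietary reference target. If eating *more of
the same food* already meets the targets, no special planning is implied.

## The model

**Energy.** Resting metabolic rate comes from a linear equation validated in
male bodybuilders,

\[ \mathrm{RMR} = 24.8 \cdot \text{mass(kg)} + 10 \quad \text{(kcal/day)}, \]

multiplied by a physical activity level (PAL) to give total daily energy
expenditure, plus a hypertrophy surplus:

\[ \mathrm{TDEE} = \mathrm{RMR}\times\mathrm{PAL}, \qquad
   \mathrm{ES} = \mathrm{TDEE}\times s, \qquad
   \mathrm{EER} = \mathrm{TDEE} + \mathrm{ES}. \]

Defaults: PAL 1.75 (the "active" category; 1.60–1.89 brackets off-season
training loads), surplus fraction \(s = 0.15\) (midpoint of the 10–20%
recommended for advanced trainees), body mass 84.5 kg (the median of the
modeled athlete population, range 75–94 kg). The slope/intercept pair is
pluggable so other linear RMR equations can be used; the default equation was
validated in males only, so female profiles trigger a warning rather than an
error.

**Scaling.** A diet profile stores nutrient densities per reference energy
(2000 kcal). Scaling multiplies every mass-unit amount by
`target_energy / reference_energy`; nutrients expressed as percent of energy
(`pct_kcal`) are scale-invariant and are carried over unchanged.
Full-precision amounts are kept alongside the reported ones, so repeated
scaling composes exactly.

**Protein and leucine.** The requirement is 1.6 g/kg/day (consensus
recommendation for maximal hypertrophy and strength), giving 135 g/day at the
median mass. The *modeled intake level* has two published routes that
disagree slightly: the explicit modeled level of 151 g/day, and the
energy-fraction route (EER × 0.145 protein energy / 4 kcal per g = 153.7
g/day). The package treats the level as an input: `protein_source =
"explicit"` (default, 151 g/day) or `"pct_energy"`, and the fitted object
records which was used. Leucine is 7.1% of plant protein (8.8% would be the
animal-protein value, selectable for comparison), distributed evenly over 4
meals (admissible 3–6), and checked inclusively (≥) against 8 g/day and
2 g/meal anabolic thresholds. Per-meal evenness is an idealization: the
source cohort has no per-meal data, so uneven distributions are out of scope.

**Adequacy.** Each reference target carries a basis (RDA, AI, CDRR,
dietary-guidelines limit) and a direction. Minima are met when the reported
scaled amount is at or above the target. Limits are met below the target —
strictly for the saturated-fat guideline (printed as "<10" % of energy),
inclusively for the sodium CDRR (a *level*, so exceeding 2300 mg/day fails);
both are configurable per row via the `strict` column. The fiber target is
energy-relative (14 g/1000 kcal) and is recomputed from the model's EER
rather than stored as a constant. Comparisons use the display-precision
amounts, matching how the published tables are read (536 vs 600 IU).
Profile nutrients without a reference are reported without a verdict, and
reference nutrients absent from a profile are listed as missing, not failed.

## Numerical choices

* **Rounding policy.** The published energy chain only reproduces if each
  stage is rounded before feeding the next: RMR to integer kcal, then TDEE
  and ES from the rounded RMR, then their sum (2106 → 3686 + 553 = 4239;
  full precision gives 4237.5). The default policy is therefore
  `report_then_propagate`, with `full_precision` available everywhere. The
  rounding rule is half-away-from-zero (3685.5 → 3686); round-half-to-even
  would break the chain. The source does not state its rule, so this is an
  inference from the printed numbers and remains overridable.
* **Divergence between policies.** The difference between the two policies
  decomposes as the RMR rounding error propagated through PAL × (1 + s) plus
  at most 0.5 kcal from each of the TDEE and ES roundings. At the default
  activity parameters this is bounded by ~2 kcal, which the tests assert;
  over the full admissible parameter space (PAL up to 2.5, surplus up to
  0.5) the analytic bound is ~2.9 kcal and the tests assert that exact
  per-input bound instead.
* **Display precision** is data, not code: each profile row carries the
  decimal places at which its scaled amount is reported (one decimal for
  omega-3 PUFA, vitamin B6 and B12; integers elsewhere), matching the
  published table.
* **Units are never converted** (IU stays IU, mcg RAE stays mcg RAE); the
  comparisons are like-for-like throughout, and a unit mismatch between
  profile and reference is an error, not a silent conversion.
* **Fiber density** is stored as 46.7 g per 2000 kcal — the cohort's
  published mean intake read as an energy-standardized density — because only
  that value reproduces the published scaled level of 99 g/day.

## Known non-reproducible cells

Four published scaled values (vitamin D 536 IU, iron 67 mg, zinc 35 mg,
potassium 8973 mg) cannot be obtained from the printed per-2000-kcal column:
proportional scaling gives 534, 68, 34 and 8974. The authors evidently scaled
unrounded densities that are not printed. The packaged fixture therefore
reproduces every *derivable* cell, and the tests pin only those; the adequacy
verdicts are unaffected (534 and 536 IU both fail the 600 IU minimum).
Similarly, the explicit protein level (151 g/day) is not derivable from the
energy-fraction method (153.7 g/day); both routes are exposed as described
above.

## The synthetic-data generators

`generate_cohort()` draws body mass and age independently and uniformly over
the published ranges (75–94 kg, 22–35 y). Uniform is the maximum-entropy
choice given only a range and a median, and its median (84.5 kg) matches the
published one, so a large cohort's median reproduces the study's energy
requirement to within a few kcal. `generate_profile()` multiplies each
density by independent lognormal noise with mean exactly 1
(\(\sigma^2 = \log(1+cv^2)\), \(\mu = -\sigma^2/2\); default cv 0.2, a
realistic between-diet coefficient of variation for FFQ-derived densities),
clipping `pct_kcal` entries to [0, 100]. One master seed drives all
generators through deterministically derived sub-seeds, and seeded calls
leave the caller's RNG stream untouched.

What the generators deliberately do **not** emulate: FFQ measurement-error
structure, sampling weights, nutrient–nutrient correlations, or per-meal
intake patterns. Passing tests on synthetic data therefore demonstrate that
the pipeline's arithmetic, directions and determinism are correct — not that
real cohort densities behave like independent lognormals.

## Problem sizes used in the test suite

Property-style tests use 50–1000 randomized cases per property, cohorts of
10^4 for median-recovery checks and 2000 replicates for noise-mean recovery;
these sizes put Monte-Carlo error many standard errors inside every asserted
tolerance while keeping the whole suite in the tens of seconds.

## A worked run

```{r}
fit <- plantbulk()
fit
```

```{r}
coef(fit)
head(render_report(fit, "csv"))
```

## Limitations

The model is a desk calculation, not a trial: it scales mean densities, so it
says nothing about inter-individual variance or prevalence of inadequacy
(no EAR cut-point modeling); it evaluates no tolerable upper limits; protein
*quality* (DIAAS) and dietary creatine are out of scope; and the hypercaloric
defaults must not be extrapolated to hypocaloric contest preparation.
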