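# plantbulk

Can an ordinary, completely plant-based diet — eaten in larger portions, with
no special planning — cover the protein, leucine and micronutrient needs of a
male bodybuilder bulking for maximal hypertrophy? `plantbulk` implements that
modeling study as a tested R pipeline for sports dietitians and nutrition
researchers.

## The model

1. **Energy.** Resting metabolic rate from a bodybuilder-validated linear
   equation, RMR = 24.8 × mass(kg) + 10 kcal/day, then
   TDEE = RMR × PAL, ES = TDEE × s, EER = TDEE + ES,
   with PAL 1.75 ("active") and surplus s = 0.15 by default. Each reported
   stage is rounded to integer kcal before feeding the next
   (`report_then_propagate`), the only chain that reproduces the published
   tables; a `full_precision` policy is available throughout.
2. **Scaling.** Nutrient densities per 2000 kcal (the packaged
   strict-vegetarian cohort profile, 18 nutrients) are multiplied by
   EER / 2000; percent-of-energy nutrients are scale-invariant.
3. **Protein & leucine.** Requirement 1.6 g/kg/day; modeled level 151 g/day
   (or derived from the 14.5% protein-energy fraction); leucine at 7.1% of
   plant protein split over 4 meals, checked against 8 g/day and 2 g/meal
   thresholds.
4. **Adequacy.** Direction-aware comparison to Dietary Reference Intakes:
   RDA/AI minima (met at or above target), the sodium CDRR limit (≤ 2300 mg)
   and the strict saturated-fat guideline (< 10 %kcal); the fiber target is
   recomputed from EER at 14 g/1000 kcal.

## Worked example

```r
library(plantbulk)
fit <- plantbulk()   # defaults reproduce the study
coef(fit)
#>                 rmr                tdee                  es                 eer
#>             2106.00             3686.00              553.00             4239.00
#> protein_requirement       protein_level    relative_protein       leucine_daily
#>              135.00              151.00                1.80               11.00
#>    leucine_per_meal
#>                2.75
fit$adequacy$failures
#> [1] "sodium"    "vitamin_d"
```

Reading: an 84.5 kg athlete needs 4239 kcal/day for a 15% bulking surplus;
scaling the plant-based profile to that energy yields 151 g/day of protein
(1.8 g/kg/day, above the 135 g/day requirement) and 2.75 g of leucine per
meal (above the 2 g anabolic trigger). All micronutrient targets are met
except vitamin D (536-ish vs 600 IU minimum) and sodium (7484 vs the 2300 mg
limit); saturated fat (5 %kcal) passes the <10% guideline.

Lower-level pieces are exported individually — `energy_requirement()`,
`scale_profile()`, `protein_plan()`, `evaluate_adequacy()`,
`generate_cohort()` / `generate_profile()` for synthetic data — and
`render_report(fit, "text" | "csv" | "json")` emits table analogues. A thin
CLI wrapper lives at `exec/plantbulk`.

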