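Package: plantbulk
Title: Nutrient Adequacy Modeling of Energy-Scaled Plant-Based Diets for
    Muscular Hypertrophy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models whether completely plant-based diets, scaled to the
    hypercaloric energy requirements of resistance-trained athletes in a
    bulking phase, supply enough protein, leucine and micronutrients.
    Implements a bodybuilder-validated linear resting metabolic rate
    prediction equation with physical-activity-level and energy-surplus
    multipliers, proportional nutrient-density scaling of cohort dietary
    profiles to a target energy intake, per-meal leucine distribution
    against anabolic thresholds, and direction-aware comparison of scaled
    nutrient levels to Dietary Reference Intake targets (RDA, AI, CDRR and
    dietary-guideline limits). Includes seeded generators for synthetic
    athlete cohorts and noisy diet profiles so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
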