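# Protein requirement, modeled level, and leucine distribution.
#
# Requirement uses the consensus 1.6 g/kg/day rate for maximal
# resistance-training gains. The modeled intake level can be supplied
# explicitly (the published modeled level, 151 g/day at 4239 kcal) or
# derived from the protein energy fraction (EER x fraction / 4 kcal per g);
# the two disagree by ~3 g/day in the source tables, so the plan records
# which pathway produced its level.

#' Daily protein requirement
#'
#' Body mass times a g/kg/day rate, rounded to integer grams. The default
#' rate (1.6 g/kg/day) is the consensus recommendation for athletes
#' maximizing hypertrophy and strength.
#'
#' @param body_mass body mass in kg (> 0).
#' @param rate requirement rate in g/kg/day (>= 0).
#' @return requirement in g/day (integer grams).
#' @export
#' @examples
#' protein_requirement(84.5)  # 135 g/day
protein_requirement <- function(body_mass, rate = 1.6) {
  check_positive(body_mass, "body_mass")
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0)
  round_half_away(body_mass * rate)
}

#' Protein level implied by an energy fraction
#'
#' Converts an energy intake and a protein energy fraction into grams of
#' protein per day at 4 kcal/g, reported to one decimal.
#'
#' @param eer energy intake in kcal/day (> 0).
#' @param fraction fraction of energy from protein, in (0, 1).
#' @param kcal_per_g energy density of protein, kcal/g.
#' @return protein in g/day, one decimal.
#' @export
#' @examples
#' protein_from_energy(4239, 0.145)  # 153.7 g/day
protein_from_energy <- function(eer, fraction = 0.145, kcal_per_g = 4) {
  check_positive(eer, "eer")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  }
  round_half_away(eer * fraction / kcal_per_g, 1)
}

#' Protein intake relative to body mass
#'
#' @param level protein intake in g/day (>= 0).
#' @param body_mass body mass in kg (> 0).
#' @return g/kg/day, one decimal.
#' @export
#' @examples
#' relative_protein(151, 84.5)  # 1.8 g/kg/day
relative_protein <- function(level, body_mass) {
  stopifnot(is.numeric(level), length(level) == 1L, level >= 0)
  check_positive(body_mass, "body_mass")
  round_half_away(level / body_mass, 1)
}

#' Daily leucine from total protein
#'
#' Leucine constitutes about 7.1% of plant proteins and 8.8% of animal
#' proteins; the plant value is the default here.
#'
#' @param protein_g_day total protein in g/day (>= 0).
#' @param fraction leucine fraction of protein, in (0, 1).
#' @param rounding `"report_then_propagate"` rounds to integer grams;
#'   `"full_precision"` returns the exact value.
#' @return leucine in g/day.
#' @export
#' @examples
#' leucine_daily(151, 0.071)  # 11 g/day
leucine_daily <- function(protein_g_day, fraction = 0.071,
                          rounding = c("report_then_propagate",
                                       "full_precision")) {
  stopifnot(is.numeric(protein_g_day), length(protein_g_day) == 1L,
            protein_g_day >= 0)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  }
  rounding <- match_rounding(rounding)
  out <- protein_g_day * fraction
  if (rounding == "report_then_propagate") out <- round_half_away(out)
  out
}

#' Leucine per meal under an even distribution
#'
#' @param leucine_g_day daily leucine in g (>= 0).
#' @param meals meals per day (integer >= 1).
#' @return g/meal, two decimals.
#' @export
#' @examples
#' leucine_per_meal(11, 4)  # 2.75 g/meal
leucine_per_meal <- function(leucine_g_day, meals = 4) {
  stopifnot(is.numeric(leucine_g_day), length(leucine_g_day) == 1L,
            leucine_g_day >= 0)
  if (!is.numeric(meals) || length(meals) != 1L || meals < 1 ||
      meals != floor(meals)) {
    stop("`meals` must be an integer >= 1", call. = FALSE)
  }
  round_half_away(leucine_g_day / meals, 2)
}

#' Build a protein and leucine plan
#'
#' Combines the requirement, the modeled intake level, relative intake, and
#' daily/per-meal leucine, then flags each anabolic threshold. The intake
#' level comes either from an explicit value (`protein_source = "explicit"`,
#' e.g. the published modeled level) or from the protein energy fraction of
#' the diet (`"pct_energy"`, needs `eer`). Meals are assumed evenly sized;
#' 3-6 meals/day is the admissible range.
#'
#' @inheritParams protein_requirement
#' @param protein_level explicit protein level in g/day (used when
#'   `protein_source = "explicit"`).
#' @param protein_source where the modeled level comes from.
#' @param eer energy intake in kcal/day (needed for `"pct_energy"`).
#' @param protein_energy_fraction fraction of energy from protein.
#' @param meals meals per day, integer in 3..6.
#' @param leucine_fraction leucine fraction of protein (plant 0.071,
#'   animal 0.088).
#' @param leucine_meal_threshold,leucine_daily_threshold anabolic trigger
#'   thresholds, g/meal and g/day.
#' @inheritParams leucine_daily
#' @return an object of class `"protein_plan"`: requirement, level,
#'   relative intake, leucine totals and `thresholds_met`, a named logical
#'   vector (see [evaluate_protein_thresholds()]).
#' @export
#' @examples
#' protein_plan(84.5, protein_level = 151)
protein_plan <- function(body_mass, protein_level = NULL,
                         protein_source = c("explicit", "pct_energy"),
                         eer = NULL, protein_energy_fraction = 0.145,
                         rate = 1.6, meals = 4, leucine_fraction = 0.071,
                         leucine_meal_threshold = 2,
                         leucine_daily_threshold = 8,
                         rounding = c("report_then_propagate",
                                      "full_precision")) {
  protein_source <- match.arg(protein_source)
  rounding <- match_rounding(rounding)
  if (!is.numeric(meals) || length(meals) != 1L || meals < 3 || meals > 6 ||
      meals != floor(meals)) {
    stop("`meals` must be an integer in 3..6", call. = FALSE)
  }
  requirement <- protein_requirement(body_mass, rate = rate)
  level <- switch(protein_source,
    explicit = {
      if (is.null(protein_level)) {
        stop("`protein_level` must be given when protein_source = 'explicit'",
             call. = FALSE)
      }
      protein_level
    },
    pct_energy = {
      if (is.null(eer)) {
        stop("`eer` must be given when protein_source = 'pct_energy'",
             call. = FALSE)
      }
      protein_from_energy(eer, protein_energy_fraction)
    }
  )
  relative <- relative_protein(level, body_mass)
  leu_day <- leucine_daily(level, leucine_fraction, rounding = rounding)
  leu_meal <- leucine_per_meal(leu_day, meals)
  plan <- structure(
    list(requirement_g_day = requirement,
         level_g_day = level,
         level_source = protein_source,
         relative_g_kg_day = relative,
         leucine_g_day = leu_day,
         leucine_g_meal = leu_meal,
         meals = meals,
         rate = rate,
         leucine_fraction = leucine_fraction,
         leucine_meal_threshold = leucine_meal_threshold,
         leucine_daily_threshold = leucine_daily_threshold,
         rounding = rounding),
    class = "protein_plan"
  )
  plan$thresholds_met <- evaluate_protein_thresholds(plan)
  plan
}

#' Check a plan against the anabolic thresholds
#'
#' Four inclusive (>=) comparisons on the reported values: total level vs
#' requirement; relative intake vs the g/kg rate; daily leucine vs the
#' daily threshold; per-meal leucine vs the per-meal trigger threshold.
#'
#' @param plan a `"protein_plan"` object.
#' @return named logical vector with elements `protein_level`,
#'   `relative_intake`, `leucine_daily`, `leucine_per_meal`.
#' @export
evaluate_protein_thresholds <- function(plan) {
  stopifnot(inherits(plan, "protein_plan"))
  c(protein_level = plan$level_g_day >= plan$requirement_g_day,
    relative_intake = plan$relative_g_kg_day >= plan$rate,
    leucine_daily = plan$leucine_g_day >= plan$leucine_daily_threshold,
    leucine_per_meal = plan$leucine_g_meal >= plan$leucine_meal_threshold)
}

#' @export
print.protein_plan <- function(x, ...) {
  flag <- function(ok) if (ok) "met" else "NOT met"
  t <- x$thresholds_met
  cat("Protein plan (level from ",
      if (x$level_source == "explicit") "explicit value" else "% of energy",
      ")\n", sep = "")
  cat(sprintf("  requirement: %s g/day (%.1f g/kg/day)\n",
              format(x$requirement_g_day), x$rate))
  cat(sprintf("  level:       %s g/day  [%s]\n",
              format(x$level_g_day), flag(t[["protein_level"]])))
  cat(sprintf("  relative:    %.1f g/kg/day  [%s]\n",
              x$relative_g_kg_day, flag(t[["relative_intake"]])))
  cat(sprintf("  leucine:     %s g/day (>= %s)  [%s]\n",
              format(x$leucine_g_day), format(x$leucine_daily_threshold),
              flag(t[["leucine_daily"]])))
  cat(sprintf("  leucine/meal: %.2f g x %d meals (>= %s)  [%s]\n",
              x$leucine_g_meal, x$meals, format(x$leucine_meal_threshold),
              flag(t[["leucine_per_meal"]])))
  invisible(x)
}
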