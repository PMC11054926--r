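# Energy requirement model: RMR -> TDEE -> surplus -> EER.
#
# The default RMR equation is the linear prediction equation validated in
# male bodybuilders, RMR = 24.8 * body mass (kg) + 10. The slope/intercept
# pair is pluggable so other linear equations can be used without touching
# the rest of the chain.

#' Resting metabolic rate from a linear prediction equation
#'
#' Predicts resting metabolic rate (RMR, kcal/day) from body mass with a
#' linear equation. The default coefficients (slope 24.8 kcal/kg/day,
#' intercept 10 kcal/day) are from the equation validated in male
#' bodybuilders; that validation covered men only, so a `sex = "female"`
#' profile triggers a warning (not an error) when the default coefficients
#' are used.
#'
#' @param body_mass body mass in kg (> 0).
#' @param slope,intercept coefficients of the linear equation
#'   (kcal/kg/day and kcal/day).
#' @param sex `"male"` or `"female"`; carried for interface completeness,
#'   unused by the equation itself.
#' @param rounding `"report_then_propagate"` (default) rounds the result to
#'   integer kcal/day, halves away from zero; `"full_precision"` returns the
#'   exact value.
#' @return RMR in kcal/day.
#' @export
#' @examples
#' rmr(84.5)  # 2106 kcal/day
#' rmr(75)    # 1870 kcal/day
rmr <- function(body_mass, slope = 24.8, intercept = 10,
                sex = c("male", "female"),
                rounding = c("report_then_propagate", "full_precision")) {
  check_positive(body_mass, "body_mass")
  sex <- match.arg(sex)
  rounding <- match_rounding(rounding)
  if (sex == "female" && slope == 24.8 && intercept == 10) {
    warning("the default RMR coefficients were validated in males only; ",
            "interpret female predictions with caution", call. = FALSE)
  }
  out <- slope * body_mass + intercept
  if (rounding == "report_then_propagate") out <- round_half_away(out)
  out
}

check_pal <- function(pal) {
  if (!is.numeric(pal) || length(pal) != 1L || !is.finite(pal) ||
      pal < 1.0 || pal > 2.5) {
    stop("`pal` must be a single number in [1.0, 2.5]", call. = FALSE)
  }
  invisible(pal)
}

check_surplus <- function(surplus_fraction) {
  if (!is.numeric(surplus_fraction) || length(surplus_fraction) != 1L ||
      !is.finite(surplus_fraction) ||
      surplus_fraction < 0 || surplus_fraction > 0.5) {
    stop("`surplus_fraction` must be a single number in [0, 0.5]",
         call. = FALSE)
  }
  invisible(surplus_fraction)
}

#' Total daily energy expenditure
#'
#' TDEE = RMR x PAL. The default PAL of 1.75 corresponds to the "active"
#' category (roughly one hour of exercise per day); values of 1.60-1.89
#' bracket off-season training loads of competitive bodybuilders.
#'
#' @param rmr resting metabolic rate, kcal/day (> 0).
#' @param pal physical activity level, dimensionless, in \[1.0, 2.5\].
#' @inheritParams rmr
#' @return TDEE in kcal/day.
#' @export
#' @examples
#' tdee(2106, pal = 1.75)  # 3686 kcal/day
tdee <- function(rmr, pal = 1.75,
                 rounding = c("report_then_propagate", "full_precision")) {
  check_positive(rmr, "rmr")
  check_pal(pal)
  rounding <- match_rounding(rounding)
  out <- rmr * pal
  if (rounding == "report_then_propagate") out <- round_half_away(out)
  out
}

#' Energy surplus for a bulking phase
#'
#' ES = RMR x PAL x surplus fraction. A 10-20% surplus above maintenance is
#' recommended for advanced trainees pursuing hypertrophy; the default is
#' the midpoint, 15%.
#'
#' @inheritParams tdee
#' @param surplus_fraction fraction of maintenance energy added as surplus,
#'   in \[0, 0.5\].
#' @return energy surplus in kcal/day.
#' @export
#' @examples
#' energy_surplus(2106, pal = 1.75, surplus_fraction = 0.15)  # 553 kcal/day
energy_surplus <- function(rmr, pal = 1.75, surplus_fraction = 0.15,
                           rounding = c("report_then_propagate",
                                        "full_precision")) {
  check_positive(rmr, "rmr")
  check_pal(pal)
  check_surplus(surplus_fraction)
  rounding <- match_rounding(rounding)
  out <- rmr * pal * surplus_fraction
  if (rounding == "report_then_propagate") out <- round_half_away(out)
  out
}

#' Estimated energy requirement for maximal hypertrophy
#'
#' Chains the three energy components: RMR from body mass, TDEE = RMR x PAL,
#' surplus ES = TDEE x surplus fraction, and EER = TDEE + ES.
#'
#' Under the default `"report_then_propagate"` policy each reported stage is
#' rounded to integer kcal/day before feeding the next (RMR first, then TDEE
#' and ES from the rounded RMR, then their sum) — the chain used for the
#' published tables. Under `"full_precision"` no rounding occurs and
#' EER = RMR x PAL x (1 + surplus) exactly.
#'
#' @inheritParams rmr
#' @inheritParams energy_surplus
#' @return an object of class `"energy_requirement"`: a list with elements
#'   `rmr`, `tdee`, `es`, `eer` (all kcal/day), `pal`, `surplus_fraction`,
#'   `rounding`.
#' @export
#' @examples
#' energy_requirement(84.5)  # RMR 2106, ES 553, EER 4239
energy_requirement <- function(body_mass, pal = 1.75, surplus_fraction = 0.15,
                               slope = 24.8, intercept = 10,
                               sex = c("male", "female"),
                               rounding = c("report_then_propagate",
                                            "full_precision")) {
  rounding <- match_rounding(rounding)
  r <- rmr(body_mass, slope = slope, intercept = intercept, sex = sex,
           rounding = rounding)
  t <- tdee(r, pal = pal, rounding = rounding)
  es <- energy_surplus(r, pal = pal, surplus_fraction = surplus_fraction,
                       rounding = rounding)
  structure(
    list(rmr = r, tdee = t, es = es, eer = t + es,
         body_mass = body_mass, pal = pal,
         surplus_fraction = surplus_fraction, rounding = rounding),
    class = "energy_requirement"
  )
}

#' @export
print.energy_requirement <- function(x, ...) {
  cat("Energy requirement (", x$rounding, ")\n", sep = "")
  cat(sprintf("  body mass: %.1f kg, PAL %.2f, surplus %.0f%%\n",
              x$body_mass, x$pal, 100 * x$surplus_fraction))
  cat(sprintf("  RMR:  %s kcal/day\n", format(x$rmr)))
  cat(sprintf("  TDEE: %s kcal/day\n", format(x$tdee)))
  cat(sprintf("  ES:   %s kcal/day\n", format(x$es)))
  cat(sprintf("  EER:  %s kcal/day\n", format(x$eer)))
  invisible(x)
}
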