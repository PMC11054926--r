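# Direction-aware comparison of scaled nutrient levels to reference targets.
#
# References carry a basis (RDA, AI, CDRR, DGA_limit) and a direction:
# minima are met when the scaled level reaches the target (>=); limits are
# met when the level stays under it (< when strict, else <=). Energy-relative
# targets (fiber, 14 g per 1000 kcal) are recomputed from the model's EER
# before comparison. Comparisons use the reported (display-precision)
# scaled amounts, matching how published tables are read.

reference_bases <- c("RDA", "AI", "CDRR", "DGA_limit")
limit_bases <- c("CDRR", "DGA_limit")

#' Read a nutrient reference table from CSV
#'
#' Columns: `nutrient_id`, `target`, `unit`, `basis` (RDA, AI, CDRR,
#' DGA_limit), `direction` (minimum or limit), `strict` (logical; a strict
#' limit uses `<`, otherwise `<=`), `energy_relative_rule` (g per 1000 kcal,
#' NA when the target is absolute). Direction must be `limit` exactly for
#' CDRR/DGA_limit bases.
#'
#' @param file path to a CSV file.
#' @return data frame of class `"nutrient_refs"`.
#' @export
read_nutrient_references <- function(file) {
  refs <- read.csv(file, stringsAsFactors = FALSE)
  validate_references(refs)
}

validate_references <- function(refs) {
  required <- c("nutrient_id", "target", "unit", "basis", "direction",
                "strict", "energy_relative_rule")
  missing <- setdiff(required, names(refs))
  if (length(missing)) {
    stop("reference table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  refs$nutrient_id <- as.character(refs$nutrient_id)
  refs$unit <- as.character(refs$unit)
  refs$basis <- as.character(refs$basis)
  refs$direction <- as.character(refs$direction)
  refs$strict <- as.logical(refs$strict)
  if (anyDuplicated(refs$nutrient_id)) {
    stop("duplicate nutrient_id in reference table", call. = FALSE)
  }
  bad_basis <- setdiff(refs$basis, reference_bases)
  if (length(bad_basis)) {
    stop("unknown basis: ", paste(bad_basis, collapse = ", "),
         "; allowed: ", paste(reference_bases, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(refs) && any(!refs$direction %in% c("minimum", "limit"))) {
    stop("`direction` must be 'minimum' or 'limit'", call. = FALSE)
  }
  inconsistent <- xor(refs$direction == "limit", refs$basis %in% limit_bases)
  if (any(inconsistent)) {
    stop("direction must be 'limit' exactly for CDRR/DGA_limit bases (rows: ",
         paste(refs$nutrient_id[inconsistent], collapse = ", "), ")",
         call. = FALSE)
  }
  if (nrow(refs) && any(!is.finite(refs$target) | refs$target <= 0)) {
    stop("`target` values must be positive", call. = FALSE)
  }
  structure(refs[, required], class = c("nutrient_refs", "data.frame"))
}

#' The packaged Dietary Reference Intake targets (males 19-30)
#'
#' RDA/AI minima for 16 vitamins, minerals and essential fatty acids, the
#' sodium CDRR limit (2300 mg/day), and the dietary-guidelines saturated-fat
#' limit (<10% of energy). Fiber's target is energy-relative
#' (14 g / 1000 kcal) and is recomputed from the model's energy requirement
#' at evaluation time.
#'
#' @return data frame of class `"nutrient_refs"` (18 rows).
#' @export
dri_references <- function() {
  read_nutrient_references(
    system.file("extdata", "dri_male_19_30.csv", package = "plantbulk")
  )
}

#' Fiber adequate intake for an energy level
#'
#' The fiber AI is energy-relative: 14 g per 1000 kcal, rounded to integer
#' grams.
#'
#' @param eer energy intake in kcal/day (> 0).
#' @return fiber AI in g/day.
#' @export
#' @examples
#' fiber_ai(4239)  # 59 g/day
fiber_ai <- function(eer) {
  check_positive(eer, "eer")
  round_half_away(14 * eer / 1000)
}

#' Evaluate a scaled profile against reference targets
#'
#' One row per reference nutrient found in the profile. Minima are met when
#' the reported scaled amount is at or above the target; limits are met when
#' it is below (strictly, for strict limits such as the saturated-fat
#' guideline) or at the target. `pct_kcal` nutrients are compared on the
#' percentage scale. Reference nutrients absent from the profile are listed
#' under `missing`, not counted as failures. Unit disagreement between
#' profile and reference is an error.
#'
#' @param scaled a `"scaled_profile"` object.
#' @param refs a `"nutrient_refs"` table (see [dri_references()]).
#' @param eer energy intake used for energy-relative targets; defaults to
#'   the profile's target energy.
#' @return an object of class `"adequacy_report"`: list with `rows` (data
#'   frame: `nutrient_id`, `scaled_amount`, `unit`, `target_value`, `basis`,
#'   `direction`, `met`), `n_met`, `n_not_met`, `failures` (ids, sorted) and
#'   `missing`.
#' @export
#' @examples
#' sp <- scale_profile(ahs2_profile(), 4239)
#' rep <- evaluate_adequacy(sp, dri_references())
#' rep$failures  # sodium, vitamin_d
evaluate_adequacy <- function(scaled, refs, eer = scaled$target_energy) {
  stopifnot(inherits(scaled, "scaled_profile"))
  refs <- validate_references(as.data.frame(refs))
  check_positive(eer, "eer")
  prof <- scaled$scaled
  present <- refs$nutrient_id %in% prof$nutrient_id
  missing <- refs$nutrient_id[!present]
  refs <- refs[present, , drop = FALSE]
  i <- match(refs$nutrient_id, prof$nutrient_id)
  mismatch <- prof$unit[i] != refs$unit
  if (any(mismatch)) {
    k <- which(mismatch)[1L]
    stop("unit mismatch for '", refs$nutrient_id[k], "': profile has '",
         prof$unit[i[k]], "', reference has '", refs$unit[k], "'",
         call. = FALSE)
  }
  target <- ifelse(is.na(refs$energy_relative_rule),
                   refs$target,
                   round_half_away(refs$energy_relative_rule * eer / 1000))
  amount <- prof$amount[i]
  met <- ifelse(refs$direction == "minimum",
                amount >= target,
                ifelse(refs$strict, amount < target, amount <= target))
  rows <- data.frame(nutrient_id = refs$nutrient_id,
                     scaled_amount = amount,
                     unit = refs$unit,
                     target_value = target,
                     basis = refs$basis,
                     direction = refs$direction,
                     met = met,
                     stringsAsFactors = FALSE)
  structure(
    list(rows = rows,
         n_met = sum(rows$met),
         n_not_met = sum(!rows$met),
         failures = sort(rows$nutrient_id[!rows$met]),
         missing = missing,
         eer = eer),
    class = "adequacy_report"
  )
}

#' @export
summary.adequacy_report <- function(object, ...) {
  structure(
    list(n_met = object$n_met,
         n_not_met = object$n_not_met,
         failures = sort(object$failures),
         missing = sort(object$missing)),
    class = "summary.adequacy_report"
  )
}

#' @export
print.summary.adequacy_report <- function(x, ...) {
  cat(sprintf("Adequacy: %d of %d targets met\n",
              x$n_met, x$n_met + x$n_not_met))
  if (length(x$failures)) {
    cat("  not met:", paste(x$failures, collapse = ", "), "\n")
  }
  if (length(x$missing)) {
    cat("  missing from profile:", paste(x$missing, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.adequacy_report <- function(x, ...) {
  rows <- x$rows
  rows$met <- ifelse(rows$met, "yes", "NO")
  cat(sprintf("Adequacy report at %s kcal/day\n", format(x$eer)))
  print(rows, row.names = FALSE)
  print(summary(x))
  invisible(x)
}
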