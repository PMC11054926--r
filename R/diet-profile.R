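# Nutrient-density profiles and proportional energy scaling.
#
# A diet profile stores nutrient densities per a reference energy intake
# (here 2000 kcal/day, the convention of the source cohort tables) plus the
# energy-fraction metadata needed downstream (protein %kcal, leucine share
# of protein). Scaling to a target energy multiplies every mass-unit amount
# by target/reference; %kcal entries are scale-invariant by construction.

profile_units <- c("g", "mg", "mcg", "mcg_RAE", "IU", "pct_kcal")

validate_densities <- function(densities) {
  required <- c("nutrient_id", "amount", "unit", "precision")
  missing <- setdiff(required, names(densities))
  if (length(missing)) {
    stop("profile table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  densities$nutrient_id <- as.character(densities$nutrient_id)
  densities$unit <- as.character(densities$unit)
  if (anyDuplicated(densities$nutrient_id)) {
    dup <- unique(densities$nutrient_id[duplicated(densities$nutrient_id)])
    stop("duplicate nutrient_id in profile: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(densities) && any(!is.finite(densities$amount) |
                             densities$amount < 0)) {
    bad <- densities$nutrient_id[!is.finite(densities$amount) |
                                 densities$amount < 0]
    stop("negative or non-finite amount for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(densities$unit, profile_units)
  if (length(unknown)) {
    stop("unknown unit(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(profile_units, collapse = ", "), call. = FALSE)
  }
  if (nrow(densities) && any(densities$precision < 0 |
                             densities$precision != floor(densities$precision))) {
    stop("`precision` must be non-negative integers", call. = FALSE)
  }
  densities[, required]
}

#' Construct a diet profile
#'
#' @param densities data frame with columns `nutrient_id`, `amount`, `unit`
#'   (one of `g`, `mg`, `mcg`, `mcg_RAE`, `IU`, `pct_kcal`) and `precision`
#'   (decimal places used when reporting the scaled amount).
#' @param reference_energy energy intake (kcal/day) the densities refer to.
#' @param name label for the profile.
#' @param protein_energy_fraction fraction of energy from protein; the
#'   default 0.145 is the mean of the strict-vegetarian cohort.
#' @param leucine_fraction leucine as a fraction of total protein; 0.071 for
#'   plant proteins (0.088 is the corresponding animal-protein value, see
#'   [leucine_daily()]).
#' @return an object of class `"diet_profile"`: list with the fields above
#'   plus `saturated_fat_energy_fraction` (derived from the `pct_kcal`
#'   saturated-fat row when present) and `fiber_density` (g per reference
#'   energy, from the fiber row when present).
#' @export
diet_profile <- function(densities, reference_energy = 2000,
                         name = "diet profile",
                         protein_energy_fraction = 0.145,
                         leucine_fraction = 0.071) {
  check_positive(reference_energy, "reference_energy")
  densities <- validate_densities(as.data.frame(densities))
  check_fraction <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || x < 0 || x > 1) {
      stop("`", nm, "` must be a fraction in [0, 1]", call. = FALSE)
    }
  }
  check_fraction(protein_energy_fraction, "protein_energy_fraction")
  check_fraction(leucine_fraction, "leucine_fraction")
  satfat <- densities$amount[densities$nutrient_id == "saturated_fat" &
                             densities$unit == "pct_kcal"]
  fiber <- densities$amount[densities$nutrient_id == "fiber"]
  structure(
    list(name = name,
         reference_energy = reference_energy,
         densities = densities,
         protein_energy_fraction = protein_energy_fraction,
         saturated_fat_energy_fraction =
           if (length(satfat)) satfat / 100 else NA_real_,
         leucine_fraction = leucine_fraction,
         fiber_density = if (length(fiber)) fiber else NA_real_),
    class = "diet_profile"
  )
}

#' Read a diet profile from CSV
#'
#' The file must have a header row and columns `nutrient_id`, `amount`,
#' `unit`, `precision` (see [diet_profile()]). Duplicate nutrient ids,
#' negative amounts and unknown units are rejected.
#'
#' @param file path to a CSV file.
#' @inheritParams diet_profile
#' @return a `"diet_profile"` object.
#' @export
read_diet_profile <- function(file, reference_energy = 2000,
                              name = basename(file),
                              protein_energy_fraction = 0.145,
                              leucine_fraction = 0.071) {
  densities <- read.csv(file, stringsAsFactors = FALSE)
  diet_profile(densities, reference_energy = reference_energy, name = name,
               protein_energy_fraction = protein_energy_fraction,
               leucine_fraction = leucine_fraction)
}

#' Write a diet profile to CSV
#'
#' Inverse of [read_diet_profile()]: writes the density table so that
#' reading it back reproduces the profile field-for-field.
#'
#' @param profile a `"diet_profile"` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_diet_profile <- function(profile, file) {
  stopifnot(inherits(profile, "diet_profile"))
  write.csv(profile$densities, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' The packaged strict-vegetarian cohort profile
#'
#' Mean nutrient densities per 2000 kcal/day of the strict-vegetarian
#' (vegan) stratum of a large cohort study, as published: 18 nutrients with
#' their units and reporting precisions. Fiber is stored at its full
#' published density (46.7 g/2000 kcal). Protein is carried as an energy
#' fraction (14.5%) rather than a density row.
#'
#' @return a `"diet_profile"` object.
#' @export
#' @examples
#' p <- ahs2_profile()
#' nrow(p$densities)  # 18
ahs2_profile <- function() {
  read_diet_profile(
    system.file("extdata", "ahs2_strict_vegetarian.csv",
                package = "plantbulk"),
    reference_energy = 2000,
    name = "AHS-2 strict vegetarian (per 2000 kcal)"
  )
}

#' Scale a diet profile to a target energy intake
#'
#' Multiplies every mass-unit nutrient amount by
#' `target_energy / reference_energy`; `pct_kcal` entries are energy
#' fractions and are carried over unchanged. Full-precision scaled amounts
#' are kept in `amount_full`; the reported `amount` is rounded to each
#' nutrient's display precision (halves away from zero).
#'
#' @param profile a `"diet_profile"` object.
#' @param target_energy target intake in kcal/day (> 0).
#' @return an object of class `"scaled_profile"`: list with `source`,
#'   `target_energy`, `scale_factor` and `scaled` (data frame with columns
#'   `nutrient_id`, `amount`, `amount_full`, `unit`, `precision`).
#' @export
#' @examples
#' sp <- scale_profile(ahs2_profile(), 4239)
#' nutrient_level(sp, "sodium")   # 7484 mg
scale_profile <- function(profile, target_energy) {
  stopifnot(inherits(profile, "diet_profile"))
  check_positive(target_energy, "target_energy")
  factor <- target_energy / profile$reference_energy
  d <- profile$densities
  full <- ifelse(d$unit == "pct_kcal", d$amount, d$amount * factor)
  reported <- mapply(round_half_away, full, d$precision)
  scaled <- data.frame(nutrient_id = d$nutrient_id,
                       amount = as.numeric(reported),
                       amount_full = as.numeric(full),
                       unit = d$unit,
                       precision = d$precision,
                       stringsAsFactors = FALSE)
  structure(
    list(source = profile, target_energy = target_energy,
         scale_factor = factor, scaled = scaled),
    class = "scaled_profile"
  )
}

#' Look up one nutrient in a scaled profile
#'
#' @param scaled a `"scaled_profile"` object.
#' @param nutrient_id nutrient name as in the profile table.
#' @return one-row data frame with `nutrient_id`, `amount` (reported at
#'   display precision), `amount_full`, `unit`, `precision`.
#' @export
nutrient_level <- function(scaled, nutrient_id) {
  stopifnot(inherits(scaled, "scaled_profile"))
  i <- match(nutrient_id, scaled$scaled$nutrient_id)
  if (is.na(i)) {
    stop("unknown nutrient_id '", nutrient_id, "'; available: ",
         paste(scaled$scaled$nutrient_id, collapse = ", "), call. = FALSE)
  }
  scaled$scaled[i, , drop = FALSE]
}

#' @export
print.diet_profile <- function(x, ...) {
  cat("Diet profile:", x$name, "\n")
  cat(sprintf("  reference energy: %s kcal/day; %d nutrients\n",
              format(x$reference_energy), nrow(x$densities)))
  cat(sprintf("  protein %.1f%% kcal, leucine %.1f%% of protein\n",
              100 * x$protein_energy_fraction, 100 * x$leucine_fraction))
  print(x$densities, row.names = FALSE)
  invisible(x)
}

#' @export
print.scaled_profile <- function(x, ...) {
  cat(sprintf("Scaled profile: %s -> %s kcal/day (factor %.4f)\n",
              x$source$name, format(x$target_energy), x$scale_factor))
  print(x$scaled[, c("nutrient_id", "amount", "unit")], row.names = FALSE)
  invisible(x)
}
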