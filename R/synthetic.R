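# Seeded generators for synthetic cohorts and noisy diet profiles.
#
# The cohort generator draws body mass and age uniformly over the published
# anthropometric ranges (uniform is the maximum-entropy choice given only a
# range and a median, and its median matches the published 84.5 kg). Profile
# noise is multiplicative lognormal with mean exactly 1, so expected
# densities equal the base profile at any coefficient of variation.

#' Published anthropometrics of the modeled athlete population
#'
#' Ranges and medians of age and body mass for competitive male
#' bodybuilders, as packaged (the inputs of the energy model).
#'
#' @return data frame with columns `parameter`, `low`, `high`, `median`.
#' @export
bodybuilder_anthropometrics <- function() {
  read.csv(system.file("extdata", "bodybuilder_anthropometrics.csv",
                       package = "plantbulk"),
           stringsAsFactors = FALSE)
}

#' Generate a synthetic athlete cohort
#'
#' Body mass and age are drawn independently and uniformly within the given
#' ranges (defaults: the published 75-94 kg and 22-35 y).
#'
#' @param n cohort size (integer >= 1).
#' @param body_mass_range,age_range length-2 ordered ranges.
#' @param seed integer seed; the caller's RNG stream is left untouched.
#' @return data frame with columns `body_mass`, `age`, `sex`.
#' @export
#' @examples
#' head(generate_cohort(5, seed = 7))
generate_cohort <- function(n, body_mass_range = c(75, 94),
                            age_range = c(22, 35), seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    stop("`n` must be an integer >= 1", call. = FALSE)
  }
  check_range <- function(r, nm) {
    if (!is.numeric(r) || length(r) != 2L || r[1] > r[2] || r[1] <= 0) {
      stop("`", nm, "` must be an ordered positive (low, high) pair",
           call. = FALSE)
    }
  }
  check_range(body_mass_range, "body_mass_range")
  check_range(age_range, "age_range")
  with_seed(seed, {
    data.frame(
      body_mass = stats::runif(n, body_mass_range[1], body_mass_range[2]),
      age = stats::runif(n, age_range[1], age_range[2]),
      sex = "male",
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a noisy synthetic diet profile
#'
#' Each density is multiplied by an independent lognormal factor with mean 1
#' and the given coefficient of variation (`sigma^2 = log(1 + cv^2)`,
#' `mu = -sigma^2 / 2`). `pct_kcal` entries are perturbed the same way and
#' then clipped to \[0, 100\]. `cv = 0` reproduces the base profile exactly.
#'
#' @param base a `"diet_profile"` to perturb.
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param seed integer seed.
#' @return a new `"diet_profile"`.
#' @export
generate_profile <- function(base, cv = 0.2, seed = NULL) {
  stopifnot(inherits(base, "diet_profile"))
  if (!is.numeric(cv) || length(cv) != 1L || cv < 0) {
    stop("`cv` must be a single number >= 0", call. = FALSE)
  }
  d <- base$densities
  factors <- if (cv == 0) {
    rep(1, nrow(d))
  } else {
    sigma <- sqrt(log(1 + cv^2))
    with_seed(seed, stats::rlnorm(nrow(d), meanlog = -sigma^2 / 2,
                                  sdlog = sigma))
  }
  d$amount <- d$amount * factors
  pct <- d$unit == "pct_kcal"
  d$amount[pct] <- pmin(pmax(d$amount[pct], 0), 100)
  diet_profile(d, reference_energy = base$reference_energy,
               name = paste0(base$name, " (synthetic, cv=", cv, ")"),
               protein_energy_fraction = base$protein_energy_fraction,
               leucine_fraction = base$leucine_fraction)
}

#' Write the fixture bundle to a directory
#'
#' Writes the packaged in-study fixtures (nutrient-density profile,
#' reference targets, cohort anthropometrics) plus one seeded synthetic
#' cohort and one seeded synthetic profile. Byte-identical across calls for
#' a fixed seed.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; generator sub-seeds are derived from it.
#' @param n synthetic cohort size.
#' @param cv noise level of the synthetic profile.
#' @return named character vector of the files written, invisibly.
#' @export
generate_fixture_bundle <- function(out_dir, seed = 1, n = 100, cv = 0.2) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory '", out_dir, "'", call. = FALSE)
  }
  paths <- c(
    profile = file.path(out_dir, "ahs2_strict_vegetarian.csv"),
    references = file.path(out_dir, "dri_male_19_30.csv"),
    anthropometrics = file.path(out_dir, "bodybuilder_anthropometrics.csv"),
    synthetic_cohort = file.path(out_dir, "synthetic_cohort.csv"),
    synthetic_profile = file.path(out_dir, "synthetic_profile.csv")
  )
  write_diet_profile(ahs2_profile(), paths[["profile"]])
  write.csv(as.data.frame(dri_references()), paths[["references"]],
            row.names = FALSE, quote = FALSE)
  write.csv(bodybuilder_anthropometrics(), paths[["anthropometrics"]],
            row.names = FALSE, quote = FALSE)
  cohort <- generate_cohort(n, seed = derive_seed(seed, 1))
  write.csv(cohort, paths[["synthetic_cohort"]], row.names = FALSE,
            quote = FALSE)
  synth <- generate_profile(ahs2_profile(), cv = cv,
                            seed = derive_seed(seed, 2))
  write_diet_profile(synth, paths[["synthetic_profile"]])
  invisible(paths)
}
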