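# Shared generators and independent oracles for property-style tests.

# A random small diet profile (valid units, non-negative amounts).
random_profile <- function(n_nutrients = 8, reference_energy = 2000) {
  units <- sample(c("g", "mg", "mcg", "mcg_RAE", "IU", "pct_kcal"),
                  n_nutrients, replace = TRUE)
  amounts <- ifelse(units == "pct_kcal",
                    runif(n_nutrients, 0, 40),
                    runif(n_nutrients, 0, 5000))
  diet_profile(
    data.frame(nutrient_id = paste0("nutrient_", seq_len(n_nutrients)),
               amount = amounts,
               unit = units,
               precision = sample(0:2, n_nutrients, replace = TRUE),
               stringsAsFactors = FALSE),
    reference_energy = reference_energy,
    name = "random synthetic profile"
  )
}

# A random reference table matching a profile's nutrients and units.
random_references <- function(profile) {
  d <- profile$densities
  direction <- sample(c("minimum", "limit"), nrow(d), replace = TRUE)
  basis <- ifelse(direction == "minimum",
                  sample(c("RDA", "AI"), nrow(d), replace = TRUE),
                  sample(c("CDRR", "DGA_limit"), nrow(d), replace = TRUE))
  data.frame(nutrient_id = d$nutrient_id,
             target = runif(nrow(d), 0.5, 8000),
             unit = d$unit,
             basis = basis,
             direction = direction,
             strict = sample(c(TRUE, FALSE), nrow(d), replace = TRUE),
             energy_relative_rule = NA_real_,
             stringsAsFactors = FALSE)
}

# Independent per-row adequacy comparison (the brute-force oracle).
adequacy_oracle <- function(scaled, refs, eer) {
  df <- scaled$scaled
  met <- logical(0)
  ids <- character(0)
  for (k in seq_len(nrow(refs))) {
    r <- refs[k, ]
    j <- which(df$nutrient_id == r$nutrient_id)
    if (!length(j)) next
    target <- if (!is.na(r$energy_relative_rule)) {
      round_half_away(r$energy_relative_rule * eer / 1000)
    } else {
      r$target
    }
    a <- df$amount[j]
    ok <- if (r$direction == "minimum") {
      a >= target
    } else if (isTRUE(r$strict)) {
      a < target
    } else {
      a <= target
    }
    ids <- c(ids, r$nutrient_id)
    met <- c(met, ok)
  }
  stats::setNames(met, ids)
}
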