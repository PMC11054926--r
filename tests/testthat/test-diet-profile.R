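test_that("the packaged cohort profile loads with its published structure", {
  p <- ahs2_profile()
  expect_s3_class(p, "diet_profile")
  expect_equal(nrow(p$densities), 18)
  expect_equal(p$reference_energy, 2000)
  expect_equal(p$protein_energy_fraction, 0.145)
  expect_equal(p$saturated_fat_energy_fraction, 0.05)
  expect_equal(p$leucine_fraction, 0.071)
  expect_equal(p$fiber_density, 46.7)
  expect_false(anyDuplicated(p$densities$nutrient_id) > 0)
})

test_that("profile validation rejects malformed tables", {
  good <- data.frame(nutrient_id = c("a", "b"), amount = c(1, 2),
                     unit = c("mg", "g"), precision = c(0, 1))
  expect_s3_class(diet_profile(good), "diet_profile")

  bad_amount <- transform(good, amount = c(-1, 2))
  expect_error(diet_profile(bad_amount), "negative")

  dup <- good
  dup$nutrient_id <- c("a", "a")
  expect_error(diet_profile(dup), "duplicate")

  bad_unit <- transform(good, unit = c("stone", "g"))
  expect_error(diet_profile(bad_unit), "unknown unit")

  expect_error(diet_profile(good[, -2]), "lacks column")
  expect_error(diet_profile(good, reference_energy = 0), "reference_energy")
})

test_that("an empty nutrient table still forms a valid profile", {
  empty <- data.frame(nutrient_id = character(), amount = numeric(),
                      unit = character(), precision = integer())
  p <- diet_profile(empty)
  expect_equal(nrow(p$densities), 0)
  s <- scale_profile(p, 3000)
  expect_equal(nrow(s$scaled), 0)
})

test_that("scaling to the study energy reproduces the published cells", {
  sp <- scale_profile(ahs2_profile(), 4239)
  expect_equal(sp$scale_factor, 4239 / 2000)
  expect_equal(nutrient_level(sp, "sodium")$amount, 7484)
  expect_equal(nutrient_level(sp, "folate")$amount, 1882)
  expect_equal(nutrient_level(sp, "fiber")$amount, 99)
  expect_equal(nutrient_level(sp, "vitamin_b12")$amount, 49.4)
  expect_equal(nutrient_level(sp, "vitamin_c")$amount, 1125)
  expect_equal(nutrient_level(sp, "magnesium")$amount, 1382)
  # pct_kcal entries are scale-invariant
  expect_equal(nutrient_level(sp, "saturated_fat")$amount, 5)
})

test_that("identity scaling leaves full-precision amounts unchanged", {
  p <- ahs2_profile()
  sp <- scale_profile(p, p$reference_energy)
  expect_equal(sp$scale_factor, 1)
  expect_equal(sp$scaled$amount_full, p$densities$amount)
  expect_equal(nutrient_level(sp, "calcium")$amount, 1156)
})

test_that("nutrient lookup errors list the available ids", {
  sp <- scale_profile(ahs2_profile(), 4239)
  expect_error(nutrient_level(sp, "unobtainium"), "unobtainium")
  expect_error(nutrient_level(sp, "unobtainium"), "sodium")
  expect_error(scale_profile(ahs2_profile(), -100), "target_energy")
})

test_that("scaling is linear and composes", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_profile()
    a <- runif(1, 0.3, 3)
    sp <- scale_profile(p, a * p$reference_energy)
    mass_units <- p$densities$unit != "pct_kcal"
    expect_equal(sp$scaled$amount_full[mass_units],
                 a * p$densities$amount[mass_units])
    expect_equal(sp$scaled$amount_full[!mass_units],
                 p$densities$amount[!mass_units])

    # scaling to E then E' on the full-precision amounts == scaling once
    e1 <- runif(1, 1000, 5000)
    e2 <- runif(1, 1000, 5000)
    mid <- p$densities
    mid$amount <- scale_profile(p, e1)$scaled$amount_full
    composed <- scale_profile(
      diet_profile(mid, reference_energy = e1), e2)$scaled$amount_full
    direct <- scale_profile(p, e2)$scaled$amount_full
    expect_equal(composed, direct)
  }
})

test_that("energy fractions survive scaling untouched", {
  p <- ahs2_profile()
  sp <- scale_profile(p, 4239)
  expect_equal(sp$source$protein_energy_fraction, p$protein_energy_fraction)
  expect_equal(sp$source$saturated_fat_energy_fraction,
               p$saturated_fat_energy_fraction)
  pct <- p$densities$unit == "pct_kcal"
  expect_equal(sp$scaled$amount_full[pct], p$densities$amount[pct])
})

test_that("write then read round-trips the packaged fixture exactly", {
  p <- ahs2_profile()
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_diet_profile(p, tmp)
  p2 <- read_diet_profile(tmp, reference_energy = p$reference_energy,
                          name = p$name)
  expect_equal(p2$densities, p$densities)
  expect_equal(p2$reference_energy, p$reference_energy)
  expect_equal(p2$protein_energy_fraction, p$protein_energy_fraction)
  expect_equal(p2$fiber_density, p$fiber_density)
})

test_that("reported scaled amounts match the brute-force oracle", {
  set.seed(23)
  for (i in 1:1000) {
    p <- random_profile(n_nutrients = 5)
    target <- runif(1, 500, 8000)
    sp <- scale_profile(p, target)
    factor <- target / p$reference_energy
    brute <- ifelse(p$densities$unit == "pct_kcal",
                    p$densities$amount,
                    p$densities$amount * factor)
    tol <- 0.5 / 10^p$densities$precision + 1e-9
    expect_true(all(abs(sp$scaled$amount - brute) <= tol))
  }
})
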