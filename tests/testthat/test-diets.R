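test_that("builtin diets transcribe the printed compositions", {
  d <- builtin_diets()
  expect_length(d, 7)
  expect_equal(d[["FISH0"]]$glucose_content, 31.3)
  expect_equal(d[["FAT45"]]$fa_profile[["C16:0"]], 39.0)
  expect_equal(d[["FISH44"]]$fa_profile[["C22:6"]], 29.2)
  expect_equal(d[["FISH0"]]$fa_profile[["C22:6"]], 0.9)
  expect_equal(d[["FAT10"]]$lipid_frac, 0.043)
  expect_equal(d[["FISH15"]]$energy_density, 22.8)
  for (diet in d) {
    expect_lte(diet$lipid_frac + diet$carb_frac + diet$protein_frac, 1)
    expect_true(all(diet$fa_profile >= 0))
    expect_lte(sum(diet$fa_profile), 100)
  }
  # FAT diets contain no marine fatty acids
  for (nm in c("FAT10", "FAT20", "FAT30", "FAT45")) {
    expect_equal(unname(d[[nm]]$fa_profile[c("C20:5", "C22:6")]), c(0, 0))
  }
})

test_that("diet_spec validates its invariants", {
  expect_error(diet_spec("X", 1.2, 0, 0, 20, c("C16:0" = 1), 10), "\\[0, 1\\]")
  expect_error(diet_spec("X", 0.5, 0.4, 0.3, 20, c("C16:0" = 1), 10),
               "sum to more than 1")
  expect_error(diet_spec("X", 0.1, 0.2, 0.3, 20, c("C16:0" = -1), 10),
               "non-negative")
  expect_error(diet_spec("X", 0.1, 0.2, 0.3, 20, c("C16:0" = 101), 10),
               "more than 100")
})

test_that("uptake-bound conversion follows the TAG mole arithmetic", {
  phys <- physiology_params(food_intake = 2.5, intestinal_dry_mass = 0.25,
                            absorption_fraction = 1, hours_per_day = 24)
  ub <- compute_uptake_bounds(builtin_diets()[["FISH44"]], phys)
  # glucose + all 8 fatty-acid TAG species
  expect_length(ub$bounds, 9)
  expect_true(all(ub$bounds >= 0))

  # hand-computed DHA bound: 2.5 g/d * 0.352 * 29.2/100 g TAG per day
  fa <- builtin_fatty_acids()[["C22:6"]]
  mw_tag <- 3 * fa$molar_mass + 92.09 - 3 * 18.02
  grams <- 2.5 * 0.352 * 29.2 / 100
  expect_equal(unname(ub$bounds[["EX_tag226_u"]]),
               grams / mw_tag * 1000 / (0.25 * 24), tolerance = 1e-12)
  # glucose by MW 180.16
  expect_equal(unname(ub$bounds[["EX_glc__D_u"]]),
               (2.5 * 31.3 / 100) / 180.16 * 1000 / (0.25 * 24),
               tolerance = 1e-12)

  # FAT diets lack the marine species: seven bounds only
  ub_fat <- compute_uptake_bounds(builtin_diets()[["FAT10"]])
  expect_length(ub_fat$bounds, 7)
})

test_that("bounds scale linearly with intake and inversely with dry mass", {
  d <- builtin_diets()[["FAT45"]]
  p1 <- physiology_params(4); p2 <- physiology_params(8)
  b1 <- compute_uptake_bounds(d, p1)$bounds
  b2 <- compute_uptake_bounds(d, p2)$bounds
  expect_equal(b2, 2 * b1, tolerance = 1e-12)
  p3 <- physiology_params(4, intestinal_dry_mass = 0.5)
  expect_equal(compute_uptake_bounds(d, p3)$bounds, b1 / 2, tolerance = 1e-12)
})

test_that("the conversion conserves total assigned TAG mass", {
  fas <- builtin_fatty_acids()
  withr::with_seed(99, {
    for (k in 1:10) {
      profile <- stats::runif(8, 0, 12)
      names(profile) <- names(fas)
      diet <- diet_spec(paste0("rand", k), lipid_frac = stats::runif(1, 0.05, 0.5),
                        carb_frac = 0.3, protein_frac = 0.15,
                        energy_density = 20, fa_profile = profile,
                        glucose_content = 30)
      phys <- physiology_params(stats::runif(1, 1, 6))
      ub <- compute_uptake_bounds(diet, phys)
      # reconstruct grams/day from each bound and its TAG molar mass
      grams <- 0
      for (lab in names(profile)) {
        fa <- fas[[lab]]
        mw <- 3 * fa$molar_mass + 92.09 - 3 * 18.02
        b <- ub$bounds[[paste0("EX_tag", gsub("[^0-9]", "", lab), "_u")]]
        grams <- grams + b * (phys$intestinal_dry_mass * phys$hours_per_day) /
          1000 * mw
      }
      expect_equal(grams,
                   phys$food_intake * diet$lipid_frac * sum(profile) / 100,
                   tolerance = 1e-9)
    }
  })
})

test_that("physiology parameters reject degenerate values", {
  expect_error(physiology_params(0), "strictly positive")
  expect_error(physiology_params(-2), "strictly positive")
  expect_error(physiology_params(2, absorption_fraction = 1.5), "\\(0, 1\\]")
  expect_error(compute_uptake_bounds(
    diet_spec("X", 0.2, 0.3, 0.2, 20, c("C99:0" = 5), 10),
    physiology_params(2)), "known species")
})

test_that("apply_diet constrains named exchanges and closes the rest", {
  m <- build_fixture_model()
  ub <- compute_uptake_bounds(builtin_diets()[["FISH0"]])
  mc <- apply_diet(m, ub)
  lb <- lower_bounds(mc)
  # DHA present at a small but nonzero ceiling (0.9 g/100 g lipid)
  expect_lt(lb[["EX_tag226_u"]], 0)
  expect_gt(lb[["EX_tag226_u"]], -0.01)
  # unnamed substrate exchange closed to uptake, oxygen still open
  expect_equal(unname(lb[["EX_lac__L_u"]]), 0)
  expect_equal(unname(lb[["EX_o2_u"]]), -1000)
  # applying the same bounds twice is idempotent
  mc2 <- apply_diet(mc, ub)
  expect_equal(lower_bounds(mc2), lb)
  expect_equal(upper_bounds(mc2), upper_bounds(mc))

  # with no uptake at all the model cannot make ATP
  empty <- structure(list(diet = "none", bounds = numeric()),
                     class = "uptake_bounds")
  m0 <- apply_diet(m, empty)
  expect_equal(fba_max_atp(m0)$objective_value, 0, tolerance = 1e-9)

  expect_error(apply_diet(m, c(EX_nope_u = 1)), "lacks exchange")
})
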