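test_that("beta-oxidation stoichiometry follows the cycle rule", {
  fas <- builtin_fatty_acids()
  # palmitate: 8 acetyl-CoA, 7 cycles, saturated
  bo <- fa_beta_oxidation_stoichiometry(fas[["C16:0"]])
  expect_equal(bo[c("acetyl_coa", "nadh", "fadh2", "cycles")],
               list(acetyl_coa = 8L, nadh = 7L, fadh2 = 7L, cycles = 7L))
  # shortest chain: a single cycle
  bo4 <- fa_beta_oxidation_stoichiometry(fatty_acid("C4:0", 4, 0))
  expect_equal(bo4[c("acetyl_coa", "nadh", "fadh2")],
               list(acetyl_coa = 2L, nadh = 1L, fadh2 = 1L))
  # DHA: each pre-existing double bond displaces one FAD step
  bo22 <- fa_beta_oxidation_stoichiometry(fas[["C22:6"]])
  expect_equal(bo22[c("acetyl_coa", "nadh", "fadh2")],
               list(acetyl_coa = 11L, nadh = 10L, fadh2 = 4L))
  # cross-check every species against cycle-by-cycle enumeration
  for (fa in fas) {
    enum <- beta_ox_enumerate(fa$carbons, fa$double_bonds)
    bo <- fa_beta_oxidation_stoichiometry(fa)
    expect_equal(bo$acetyl_coa, enum$acetyl_coa, info = fa$label)
    expect_equal(bo$nadh, enum$nadh, info = fa$label)
    expect_equal(bo$fadh2, enum$fadh2, info = fa$label)
    expect_equal(bo$cycles, enum$cycles, info = fa$label)
  }
  expect_error(fatty_acid("C15:0", 15), "even")
  expect_error(fatty_acid("C4:2", 4, 2), "double_bonds")
})

test_that("fixture has the expected compartments, reactions and gap-free topology", {
  m <- build_fixture_model()
  expect_setequal(unique(vapply(m$metabolites, `[[`, "", "compartment")),
                  c("u", "c", "m"))
  need <- c("PDHm", "CSm", "ICDHxm", "AKGDm",
            paste0("FAOXC", c(140, 160, 180, 181, 182, 183, 205, 226)),
            "GLYCL", "MASLm", "G3PDm", "NADH2_u10m", "FADH2ETC", "ATPS4m",
            "DM_atp_c", "EX_o2_u", "EX_co2_u", "EX_h2o_u", "EX_pi_u", "EX_h_u",
            paste0("CPT1", c(140, 160, 180, 181, 182, 183, 205, 226)),
            paste0("CACT", c(140, 160)), paste0("CPT2", c(140, 160)))
  expect_true(all(need %in% reaction_ids(m)))
  expect_identical(m$objective_reaction, "DM_atp_c")
  expect_length(find_dead_end_metabolites(m), 0)

  # marine flag semantics
  m0 <- build_fixture_model(include_marine_fa = FALSE)
  expect_false(any(c("FAOXC205", "FAOXC226") %in% reaction_ids(m0)))
  expect_length(find_dead_end_metabolites(m0), 0)
})

test_that("fixture is elementally balanced and its FAOX rows match the rule", {
  m <- build_fixture_model()
  bal <- check_elemental_balance(m, elements = c("C", "H", "N", "O", "P", "S"))
  expect_true(attr(bal, "balanced"))

  for (fa in builtin_fatty_acids()) {
    bo <- fa_beta_oxidation_stoichiometry(fa)
    r <- get_reaction(m, paste0("FAOXC", gsub("[^0-9]", "", fa$label)))
    expect_equal(unname(r$stoichiometry[["accoa_m"]]), bo$acetyl_coa)
    expect_equal(unname(r$stoichiometry[["nadh_m"]]), bo$nadh)
    expect_equal(unname(r$stoichiometry[["nad_m"]]), -bo$nadh)
    if (bo$fadh2 > 0) {
      expect_equal(unname(r$stoichiometry[["fadh2_m"]]), bo$fadh2)
    }
  }
})

test_that("contradictory fixture overrides are rejected", {
  expect_error(fixture_config(h_per_nadh = -1), "positive")
  expect_error(fixture_config(h_per_atp = 0), "positive")
  expect_error(build_fixture_model(config = list(h_per_fadh2 = -2)), "positive")
})

test_that("maximal ATP yields equal the proton-ledger closed forms", {
  m <- build_fixture_model()
  ex_ids <- reaction_ids(m)[is_exchange(m)]
  base <- set_bounds(m, ex_ids, lower = 0)
  base <- set_bounds(base, c("EX_o2_u", "EX_h2o_u", "EX_pi_u", "EX_h_u"),
                     lower = -1000)

  glc <- set_bounds(base, "EX_glc__D_u", lower = -1)
  expect_equal(fba_max_atp(glc)$objective_value, oracle_atp_per_glucose(),
               tolerance = 1e-7)

  tag <- set_bounds(base, "EX_tag160_u", lower = -1)
  atp_tag <- fba_max_atp(tag)$objective_value
  expect_equal(atp_tag, oracle_atp_per_tag(16, 0), tolerance = 1e-7)
  expect_gt(atp_tag, oracle_atp_per_glucose())

  # closing every exchange forces a zero optimum
  expect_equal(fba_max_atp(set_bounds(m, ex_ids, lower = 0, upper = 0)
                           )$objective_value, 0, tolerance = 1e-9)

  # yields respond to the configured proton stoichiometry
  m2 <- build_fixture_model(config = fixture_config(h_per_nadh = 6,
                                                    h_per_fadh2 = 4,
                                                    h_per_atp = 3))
  base2 <- set_bounds(m2, reaction_ids(m2)[is_exchange(m2)], lower = 0)
  base2 <- set_bounds(base2, c("EX_o2_u", "EX_h2o_u", "EX_pi_u", "EX_h_u"),
                      lower = -1000)
  glc2 <- set_bounds(base2, "EX_glc__D_u", lower = -1)
  expect_equal(fba_max_atp(glc2)$objective_value,
               oracle_atp_per_glucose(hn = 6, hf = 4, ha = 3),
               tolerance = 1e-7)
})

test_that("anaerobic and synthase-free yields collapse to substrate-level ATP", {
  m <- build_fixture_model()
  ex_ids <- reaction_ids(m)[is_exchange(m)]
  base <- set_bounds(m, ex_ids, lower = 0)
  base <- set_bounds(base, c("EX_o2_u", "EX_h2o_u", "EX_pi_u", "EX_h_u"),
                     lower = -1000)
  glc <- set_bounds(base, "EX_glc__D_u", lower = -1)

  # no oxygen: glycolysis + lactate secretion only, 2 ATP per glucose
  expect_equal(fba_max_atp(set_bounds(glc, "EX_o2_u", lower = 0, upper = 1000)
                           )$objective_value, 2, tolerance = 1e-7)
  # no ATP synthase: same substrate-level ceiling
  expect_equal(fba_max_atp(remove_reactions(glc, "ATPS4m"))$objective_value,
               2, tolerance = 1e-7)
})

test_that("widening a substrate exchange bound never decreases maximal ATP", {
  m <- build_fixture_model()
  ub <- compute_uptake_bounds(builtin_diets()[["FISH0"]])
  mc <- apply_diet(m, ub)
  base_obj <- fba_max_atp(mc)$objective_value
  for (rxn in c("EX_glc__D_u", "EX_tag160_u", "EX_tag226_u")) {
    widened <- set_bounds(mc, rxn, lower = lower_bounds(mc)[[rxn]] * 2)
    expect_gte(fba_max_atp(widened)$objective_value, base_obj - 1e-8)
  }
})
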