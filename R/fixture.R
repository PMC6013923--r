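#' Configuration of the reduced enterocyte mitochondrial network
#'
#' The proton stoichiometries follow standard textbook values: complexes
#' I+III+IV pump 10 H+ per NADH (4+4+2), complexes III+IV pump 6 H+ per
#' FADH2-equivalent, and ATP synthesis consumes an effective 4 H+ per
#' cytosolic ATP (3 at the synthase plus 1 for phosphate/adenine-nucleotide
#' transport), giving P/O ratios of 2.5 and 1.5.
#'
#' @param h_per_nadh Protons pumped from matrix to cytosol per NADH oxidized.
#' @param h_per_fadh2 Protons pumped per FADH2-equivalent oxidized.
#' @param h_per_atp Protons of the gradient consumed per cytosolic ATP.
#' @param default_bound Magnitude of the default flux bounds
#'   (mmol g-1 h-1); reversible reactions get `[-default_bound,
#'   default_bound]`, irreversible `[0, default_bound]`.
#' @param drain_open Open the optional biomass-like acetyl-CoA drain that
#'   stands in for the phospholipid/heme biosynthetic branches (default
#'   closed; the reported fluxes do not exercise it).
#' @return List of class `"fixture_config"`.
#' @export
fixture_config <- function(h_per_nadh = 10, h_per_fadh2 = 6, h_per_atp = 4,
                           default_bound = 1000, drain_open = FALSE) {
  cfg <- list(h_per_nadh = h_per_nadh, h_per_fadh2 = h_per_fadh2,
              h_per_atp = h_per_atp, default_bound = default_bound,
              drain_open = isTRUE(drain_open))
  for (field in c("h_per_nadh", "h_per_fadh2", "h_per_atp", "default_bound")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("fixture config error: '", field, "' must be a positive number")
    }
  }
  structure(cfg, class = "fixture_config")
}

# CnH(2n)O... formula strings for the lipid species
fa_formula <- function(fa) {
  sprintf("C%dH%dO2", fa$carbons, 2 * fa$carbons - 2 * fa$double_bonds)
}
tag_formula <- function(fa) {
  sprintf("C%dH%dO6", 3 * fa$carbons + 3,
          6 * fa$carbons - 6 * fa$double_bonds + 2)
}
facoa_formula <- function(fa) {
  sprintf("C%dH%dN7O17P3S", fa$carbons + 21,
          2 * fa$carbons - 2 * fa$double_bonds + 34)
}
facrn_formula <- function(fa) {
  sprintf("C%dH%dNO4", fa$carbons + 7,
          2 * fa$carbons - 2 * fa$double_bonds + 13)
}

#' Build the reduced enterocyte mitochondrial fixture model
#'
#' Constructs a fully elementally balanced, three-compartment (luminal "u",
#' cytosolic "c", mitochondrial matrix "m") constraint-based network of
#' enterocyte mitochondrial energy metabolism: per-species luminal uniform-TAG
#' exchange and hydrolysis, fatty-acid activation and the Cpt1a /
#' Slc25a20 / Cpt2 carnitine shuttle, lumped matrix beta-oxidation
#' (reactions `FAOXC140` ... `FAOXC226`), lumped glycolysis with lactate
#' fermentation, pyruvate dehydrogenase (`PDHm`) and the full TCA cycle
#' (`CSm`, `ACONTm`, `ICDHxm`, `AKGDm`, `SUCOASm`, `SUCD1m`, `FUMm`,
#' `MDHm`), malate-aspartate and glycerol-phosphate shuttles, proton-pumping
#' electron transport, ATP synthesis consuming the gradient, and a cytosolic
#' ATP demand reaction set as the flux-balance objective.
#'
#' @param include_marine_fa Include the marine species EPA (C20:5) and DHA
#'   (C22:6) and their `FAOXC205`/`FAOXC226` reactions.
#' @param config A [fixture_config()].
#' @return A validated `"metabolic_model"`.
#' @export
build_fixture_model <- function(include_marine_fa = TRUE,
                                config = fixture_config()) {
  if (!inherits(config, "fixture_config")) config <- do.call(fixture_config, config)
  B <- config$default_bound
  fas <- builtin_fatty_acids(include_marine = include_marine_fa)

  mets <- list(); rxns <- list()
  add_met <- function(id, name, formula) {
    mets[[id]] <<- metabolite(id, name = name, formula = formula)
  }
  add_rxn <- function(id, stoich, name = id, rev = FALSE, lb = NULL, ub = NULL,
                      gene_rule = "", subsystem = "") {
    rxns[[id]] <<- reaction(
      id, stoich, name = name,
      lower_bound = if (is.null(lb)) (if (rev) -B else 0) else lb,
      upper_bound = if (is.null(ub)) B else ub,
      gene_rule = gene_rule, subsystem = subsystem)
  }

  ## -- shared small metabolites ------------------------------------------
  core <- list(
    glc__D = c("D-glucose", "C6H12O6"),
    pyr    = c("pyruvate", "C3H4O3"),
    lac__L = c("L-lactate", "C3H6O3"),
    glyc   = c("glycerol", "C3H8O3"),
    o2     = c("oxygen", "O2"),
    co2    = c("carbon dioxide", "CO2"),
    h2o    = c("water", "H2O"),
    pi     = c("inorganic phosphate", "H3PO4"),
    h      = c("proton", "H")
  )
  for (base in names(core)) {
    cmp_for <- switch(base,
                      glc__D = c("u", "c"), pyr = c("c", "m"),
                      lac__L = c("u", "c"), glyc = c("u", "c"),
                      c("u", "c", "m"))
    for (cmp in cmp_for) {
      add_met(paste0(base, "_", cmp), core[[base]][1], core[[base]][2])
    }
  }
  cyto <- list(
    glyc3p = c("sn-glycerol 3-phosphate", "C3H9O6P"),
    dhap   = c("dihydroxyacetone phosphate", "C3H7O6P"),
    amp    = c("AMP", "C10H14N5O7P"),
    ppi    = c("pyrophosphate", "H4P2O7"),
    crn    = c("L-carnitine", "C7H15NO3"),
    coa    = c("coenzyme A", "C21H36N7O16P3S"),
    nad    = c("NAD+", "C21H27N7O14P2"),
    nadh   = c("NADH", "C21H28N7O14P2"),
    atp    = c("ATP", "C10H16N5O13P3"),
    adp    = c("ADP", "C10H15N5O10P2")
  )
  for (base in names(cyto)) add_met(paste0(base, "_c"), cyto[[base]][1], cyto[[base]][2])
  mito <- list(
    accoa  = c("acetyl-CoA", "C23H38N7O17P3S"),
    coa    = c("coenzyme A", "C21H36N7O16P3S"),
    nad    = c("NAD+", "C21H27N7O14P2"),
    nadh   = c("NADH", "C21H28N7O14P2"),
    fad    = c("FAD", "C27H33N9O15P2"),
    fadh2  = c("FADH2", "C27H35N9O15P2"),
    atp    = c("ATP", "C10H16N5O13P3"),
    adp    = c("ADP", "C10H15N5O10P2"),
    crn    = c("L-carnitine", "C7H15NO3"),
    oaa    = c("oxaloacetate", "C4H4O5"),
    cit    = c("citrate", "C6H8O7"),
    icit   = c("isocitrate", "C6H8O7"),
    akg    = c("2-oxoglutarate", "C5H6O5"),
    succoa = c("succinyl-CoA", "C25H40N7O19P3S"),
    succ   = c("succinate", "C4H6O4"),
    fum    = c("fumarate", "C4H4O4"),
    mal__L = c("L-malate", "C4H6O5")
  )
  for (base in names(mito)) add_met(paste0(base, "_m"), mito[[base]][1], mito[[base]][2])

  ## -- per-fatty-acid species --------------------------------------------
  for (lab in names(fas)) {
    fa <- fas[[lab]]; code <- fa_code(lab)
    add_met(paste0("tag", code, "_u"), paste("uniform TAG of", lab), tag_formula(fa))
    add_met(paste0("fa", code, "_u"), paste("free", lab), fa_formula(fa))
    add_met(paste0("fa", code, "_c"), paste("free", lab), fa_formula(fa))
    add_met(paste0("fa", code, "coa_c"), paste(lab, "acyl-CoA"), facoa_formula(fa))
    add_met(paste0("fa", code, "coa_m"), paste(lab, "acyl-CoA"), facoa_formula(fa))
    add_met(paste0("fa", code, "crn_c"), paste(lab, "acyl-carnitine"), facrn_formula(fa))
    add_met(paste0("fa", code, "crn_m"), paste(lab, "acyl-carnitine"), facrn_formula(fa))
  }

  ## -- exchanges ----------------------------------------------------------
  ex <- function(met, name) {
    add_rxn(paste0("EX_", met), stats::setNames(-1, met), name = name,
            lb = -B, ub = B, subsystem = "Exchange")
  }
  ex("glc__D_u", "D-glucose exchange")
  for (lab in names(fas)) {
    ex(paste0("tag", fa_code(lab), "_u"),
       paste("uniform TAG exchange,", lab))
  }
  ex("o2_u", "oxygen exchange"); ex("co2_u", "carbon dioxide exchange")
  ex("h2o_u", "water exchange"); ex("pi_u", "phosphate exchange")
  ex("h_u", "proton exchange"); ex("lac__L_u", "L-lactate exchange")

  ## -- luminal lipolysis and absorption ------------------------------------
  for (lab in names(fas)) {
    code <- fa_code(lab)
    add_rxn(paste0("LIPH", code),
            stats::setNames(c(-1, -3, 3, 1),
                            c(paste0("tag", code, "_u"), "h2o_u",
                              paste0("fa", code, "_u"), "glyc_u")),
            name = paste("luminal TAG hydrolysis,", lab),
            gene_rule = "Pnlip", subsystem = "Lipolysis")
    add_rxn(paste0("FAt", code),
            stats::setNames(c(-1, 1),
                            paste0("fa", code, c("_u", "_c"))),
            name = paste("fatty acid absorption,", lab),
            gene_rule = "Cd36 or Slc27a4", subsystem = "Transport")
  }
  add_rxn("GLCt1", c(glc__D_u = -1, glc__D_c = 1),
          name = "glucose absorption", gene_rule = "Slc5a1 or Slc2a2",
          subsystem = "Transport")
  add_rxn("GLYCt", c(glyc_u = -1, glyc_c = 1),
          name = "glycerol absorption", gene_rule = "Aqp7",
          subsystem = "Transport")

  ## -- small-molecule transport -------------------------------------------
  add_rxn("O2t", c(o2_u = -1, o2_c = 1), rev = TRUE,
          name = "oxygen transport", subsystem = "Transport")
  add_rxn("O2tm", c(o2_c = -1, o2_m = 1), rev = TRUE,
          name = "oxygen diffusion, mitochondrial", subsystem = "Transport")
  add_rxn("CO2t", c(co2_c = -1, co2_u = 1),
          name = "carbon dioxide release", subsystem = "Transport")
  add_rxn("CO2tm", c(co2_m = -1, co2_c = 1),
          name = "carbon dioxide release, mitochondrial",
          subsystem = "Transport")
  add_rxn("H2Ot", c(h2o_u = -1, h2o_c = 1), rev = TRUE,
          name = "water transport", subsystem = "Transport")
  add_rxn("H2Otm", c(h2o_c = -1, h2o_m = 1), rev = TRUE,
          name = "water diffusion, mitochondrial", subsystem = "Transport")
  add_rxn("PIt", c(pi_u = -1, pi_c = 1), rev = TRUE,
          name = "phosphate transport", subsystem = "Transport")
  add_rxn("PIt2m", c(pi_c = -1, h_c = -1, pi_m = 1, h_m = 1),
          name = "phosphate carrier (H+ symport)", gene_rule = "Slc25a3",
          subsystem = "Transport")
  add_rxn("Ht", c(h_u = -1, h_c = 1), rev = TRUE,
          name = "proton exchange, brush border", subsystem = "Transport")
  add_rxn("L_LACt", c(lac__L_c = -1, lac__L_u = 1),
          name = "lactate secretion", gene_rule = "Slc16a1",
          subsystem = "Transport")
  add_rxn("PYRt2m", c(pyr_c = -1, h_c = -1, pyr_m = 1, h_m = 1),
          name = "mitochondrial pyruvate carrier (H+ symport)",
          gene_rule = "Mpc1 and Mpc2", subsystem = "Transport")
  add_rxn("ATPtm", c(atp_m = -1, adp_c = -1, atp_c = 1, adp_m = 1),
          name = "adenine nucleotide translocase", gene_rule = "Slc25a4",
          subsystem = "Transport")

  ## -- glycolysis, fermentation, glycerol utilization ----------------------
  add_rxn("GLYCL",
          c(glc__D_c = -1, adp_c = -2, pi_c = -2, nad_c = -2,
            pyr_c = 2, atp_c = 2, nadh_c = 2, h2o_c = 2, h_c = 2),
          name = "glycolysis (lumped, glucose to pyruvate)",
          gene_rule = "Hk1 and Gpi1 and Pfkl and Aldoa and Tpi1 and Gapdh and Pgk1 and Pgam1 and Eno1 and Pkm",
          subsystem = "Glycolysis")
  add_rxn("DHAPPYR",
          c(dhap_c = -1, adp_c = -2, pi_c = -1, nad_c = -1,
            pyr_c = 1, atp_c = 2, nadh_c = 1, h2o_c = 1, h_c = 1),
          name = "lower glycolysis (lumped, DHAP to pyruvate)",
          gene_rule = "Tpi1 and Gapdh and Pgk1 and Pgam1 and Eno1 and Pkm",
          subsystem = "Glycolysis")
  add_rxn("LDH_L",
          c(pyr_c = -1, nadh_c = -1, h_c = -1, lac__L_c = 1, nad_c = 1),
          rev = TRUE, name = "L-lactate dehydrogenase",
          gene_rule = "Ldha or Ldhb", subsystem = "Fermentation")
  add_rxn("GLYK", c(glyc_c = -1, atp_c = -1, glyc3p_c = 1, adp_c = 1),
          name = "glycerol kinase", gene_rule = "Gk",
          subsystem = "Glycolysis")
  add_rxn("G3PD2c",
          c(dhap_c = -1, nadh_c = -1, h_c = -1, glyc3p_c = 1, nad_c = 1),
          rev = TRUE, name = "glycerol-3-phosphate dehydrogenase, cytosolic",
          gene_rule = "Gpd1", subsystem = "Shuttles")

  ## -- redox shuttles into the matrix --------------------------------------
  add_rxn("MASLm", c(nadh_c = -1, nad_m = -1, nad_c = 1, nadh_m = 1),
          name = "malate-aspartate shuttle (lumped)",
          gene_rule = "Mdh1 and Mdh2 and Got1 and Got2 and Slc25a11 and Slc25a12",
          subsystem = "Shuttles")
  add_rxn("G3PDm", c(glyc3p_c = -1, fad_m = -1, dhap_c = 1, fadh2_m = 1),
          name = "glycerol-3-phosphate dehydrogenase, mitochondrial",
          gene_rule = "Gpd2", subsystem = "Shuttles")

  ## -- fatty-acid activation and carnitine shuttle --------------------------
  add_rxn("ADK1", c(amp_c = -1, atp_c = -1, adp_c = 2), rev = TRUE,
          name = "adenylate kinase", gene_rule = "Ak1",
          subsystem = "Lipid activation")
  add_rxn("PPA", c(ppi_c = -1, h2o_c = -1, pi_c = 2),
          name = "inorganic pyrophosphatase", gene_rule = "Ppa1",
          subsystem = "Lipid activation")
  for (lab in names(fas)) {
    code <- fa_code(lab)
    add_rxn(paste0("FACOAL", code),
            stats::setNames(c(-1, -1, -1, 1, 1, 1),
                            c(paste0("fa", code, "_c"), "coa_c", "atp_c",
                              paste0("fa", code, "coa_c"), "amp_c", "ppi_c")),
            name = paste("long-chain fatty-acid CoA ligase,", lab),
            gene_rule = "Acsl1 or Acsl3 or Acsl5",
            subsystem = "Lipid activation")
    add_rxn(paste0("CPT1", code),
            stats::setNames(c(-1, -1, 1, 1),
                            c(paste0("fa", code, "coa_c"), "crn_c",
                              paste0("fa", code, "crn_c"), "coa_c")),
            name = paste("carnitine palmitoyltransferase 1,", lab),
            gene_rule = "Cpt1a", subsystem = "Carnitine shuttle")
    add_rxn(paste0("CACT", code),
            stats::setNames(c(-1, -1, 1, 1),
                            c(paste0("fa", code, "crn_c"), "crn_m",
                              paste0("fa", code, "crn_m"), "crn_c")),
            rev = TRUE,
            name = paste("carnitine/acylcarnitine translocase,", lab),
            gene_rule = "Slc25a20", subsystem = "Carnitine shuttle")
    add_rxn(paste0("CPT2", code),
            stats::setNames(c(-1, -1, 1, 1),
                            c(paste0("fa", code, "crn_m"), "coa_m",
                              paste0("fa", code, "coa_m"), "crn_m")),
            name = paste("carnitine palmitoyltransferase 2,", lab),
            gene_rule = "Cpt2", subsystem = "Carnitine shuttle")
  }

  ## -- matrix beta-oxidation ------------------------------------------------
  for (lab in names(fas)) {
    fa <- fas[[lab]]; code <- fa_code(lab)
    bo <- fa_beta_oxidation_stoichiometry(fa)
    y <- bo$cycles
    add_rxn(faox_id(lab),
            stats::setNames(
              c(-1, -y, -y, -bo$fadh2, -y,
                bo$acetyl_coa, y, bo$fadh2, y),
              c(paste0("fa", code, "coa_m"), "coa_m", "nad_m", "fad_m",
                "h2o_m", "accoa_m", "nadh_m", "fadh2_m", "h_m")),
            name = paste("mitochondrial beta-oxidation,", lab),
            gene_rule = "Acadvl and Hadha and Hadhb and Acaa2",
            subsystem = "Beta-oxidation")
  }

  ## -- pyruvate dehydrogenase and TCA cycle ---------------------------------
  add_rxn("PDHm",
          c(pyr_m = -1, coa_m = -1, nad_m = -1,
            accoa_m = 1, co2_m = 1, nadh_m = 1, h_m = 1),
          name = "pyruvate dehydrogenase",
          gene_rule = "Pdha1 and Pdhb and Dlat and Dld",
          subsystem = "TCA cycle")
  add_rxn("CSm", c(accoa_m = -1, oaa_m = -1, h2o_m = -1, cit_m = 1, coa_m = 1),
          name = "citrate synthase", gene_rule = "Cs", subsystem = "TCA cycle")
  add_rxn("ACONTm", c(cit_m = -1, icit_m = 1), rev = TRUE,
          name = "aconitase", gene_rule = "Aco2", subsystem = "TCA cycle")
  add_rxn("ICDHxm",
          c(icit_m = -1, nad_m = -1, akg_m = 1, co2_m = 1, nadh_m = 1, h_m = 1),
          name = "isocitrate dehydrogenase (NAD+)",
          gene_rule = "Idh3a and Idh3b and Idh3g", subsystem = "TCA cycle")
  add_rxn("AKGDm",
          c(akg_m = -1, coa_m = -1, nad_m = -1,
            succoa_m = 1, co2_m = 1, nadh_m = 1, h_m = 1),
          name = "2-oxoglutarate dehydrogenase",
          gene_rule = "Ogdh and Dlst and Dld", subsystem = "TCA cycle")
  add_rxn("SUCOASm",
          c(succoa_m = -1, adp_m = -1, pi_m = -1,
            succ_m = 1, coa_m = 1, atp_m = 1),
          rev = TRUE, name = "succinyl-CoA synthetase",
          gene_rule = "Suclg1 and Sucla2", subsystem = "TCA cycle")
  add_rxn("SUCD1m", c(succ_m = -1, fad_m = -1, fum_m = 1, fadh2_m = 1),
          rev = TRUE, name = "succinate dehydrogenase",
          gene_rule = "Sdha and Sdhb and Sdhc and Sdhd",
          subsystem = "TCA cycle")
  add_rxn("FUMm", c(fum_m = -1, h2o_m = -1, mal__L_m = 1), rev = TRUE,
          name = "fumarase", gene_rule = "Fh1", subsystem = "TCA cycle")
  add_rxn("MDHm", c(mal__L_m = -1, nad_m = -1, oaa_m = 1, nadh_m = 1, h_m = 1),
          rev = TRUE, name = "malate dehydrogenase",
          gene_rule = "Mdh2", subsystem = "TCA cycle")

  ## -- oxidative phosphorylation -------------------------------------------
  hn <- config$h_per_nadh; hf <- config$h_per_fadh2; ha <- config$h_per_atp
  add_rxn("NADH2_u10m",
          c(nadh_m = -1, h_m = -(hn + 1), o2_m = -0.5,
            nad_m = 1, h_c = hn, h2o_m = 1),
          name = "NADH oxidation, complexes I+III+IV (lumped, proton pumping)",
          gene_rule = "Ndufs1 and Uqcrc1 and Cox4i1",
          subsystem = "Oxidative phosphorylation")
  add_rxn("FADH2ETC",
          c(fadh2_m = -1, h_m = -hf, o2_m = -0.5,
            fad_m = 1, h_c = hf, h2o_m = 1),
          name = "FADH2 oxidation, complexes III+IV (lumped, proton pumping)",
          gene_rule = "Uqcrc1 and Cox4i1",
          subsystem = "Oxidative phosphorylation")
  add_rxn("ATPS4m",
          c(adp_c = -1, pi_c = -1, h_c = -ha, atp_c = 1, h2o_c = 1, h_m = ha),
          name = "ATP synthase (plus adenine-nucleotide/phosphate transport, lumped)",
          gene_rule = "Atp5f1a and Atp5f1b",
          subsystem = "Oxidative phosphorylation")

  ## -- demands --------------------------------------------------------------
  add_rxn("DM_atp_c", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1),
          name = "cytosolic ATP demand", subsystem = "Demand")
  add_rxn("DM_accoa_m", c(accoa_m = -1, coa_m = 1),
          lb = 0, ub = if (config$drain_open) B else 0,
          name = "biosynthetic acetyl-CoA drain (phospholipid/heme branch stand-in)",
          subsystem = "Demand")

  model <- metabolic_model(unname(mets), unname(rxns),
                           objective_reaction = "DM_atp_c",
                           id = if (include_marine_fa) "mitoflux_fixture"
                                else "mitoflux_fixture_nomarine")
  model$config <- config
  model
}
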