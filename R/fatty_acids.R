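#' Create a fatty-acid species record
#'
#' @param label Standard shorthand, e.g. `"C16:0"`, `"C20:5"`, `"C22:6"`.
#' @param carbons Even, positive chain length.
#' @param double_bonds Number of C=C double bonds; must be < `carbons / 2`.
#' @param molar_mass Molar mass of the free acid in g/mol; computed from the
#'   composition (CnH(2n-2d)O2) when omitted.
#' @return A list of class `"fatty_acid"`.
#' @export
fatty_acid <- function(label, carbons, double_bonds = 0, molar_mass = NULL) {
  carbons <- as.integer(carbons); double_bonds <- as.integer(double_bonds)
  if (carbons <= 0 || carbons %% 2 != 0) {
    stop("unsupported fatty-acid species '", label,
         "': carbon count must be even and positive (odd-chain species are",
         " not modelled)")
  }
  if (double_bonds < 0 || double_bonds >= carbons / 2) {
    stop("fatty acid '", label, "': double_bonds must lie in [0, carbons/2)")
  }
  if (is.null(molar_mass)) {
    h <- 2 * carbons - 2 * double_bonds
    molar_mass <- carbons * 12.011 + h * 1.008 + 2 * 15.999
  }
  structure(list(label = label, carbons = carbons,
                 double_bonds = double_bonds, molar_mass = molar_mass),
            class = "fatty_acid")
}

#' The eight dietary fatty-acid species of the diet studies
#'
#' Myristic (C14:0), palmitic (C16:0), stearic (C18:0), oleic (C18:1),
#' linoleic (C18:2) and alpha-linolenic (C18:3) acid span the palm/soy-oil
#' based diets; eicosapentaenoic (EPA, C20:5) and docosahexaenoic (DHA,
#' C22:6) acid are the marine species of the fish-oil diets.
#'
#' @param include_marine Include EPA and DHA (default `TRUE`).
#' @return Named list of [fatty_acid()] records keyed by label.
#' @export
builtin_fatty_acids <- function(include_marine = TRUE) {
  fas <- list(
    "C14:0" = fatty_acid("C14:0", 14, 0, 228.37),
    "C16:0" = fatty_acid("C16:0", 16, 0, 256.42),
    "C18:0" = fatty_acid("C18:0", 18, 0, 284.48),
    "C18:1" = fatty_acid("C18:1", 18, 1, 282.46),
    "C18:2" = fatty_acid("C18:2", 18, 2, 280.45),
    "C18:3" = fatty_acid("C18:3", 18, 3, 278.43)
  )
  if (include_marine) {
    fas[["C20:5"]] <- fatty_acid("C20:5", 20, 5, 302.45)
    fas[["C22:6"]] <- fatty_acid("C22:6", 22, 6, 328.49)
  }
  fas
}

#' Mitochondrial beta-oxidation stoichiometry of a fatty acid
#'
#' Complete matrix beta-oxidation of a Cn:d acyl-CoA runs `n/2 - 1` cycles
#' and yields `n/2` acetyl-CoA. Each cycle reduces one NAD+; the initial
#' FAD-dependent dehydrogenation is bypassed at each pre-existing double
#' bond (isomerase route), so FADH2 output is `cycles - d`. The
#' NADPH-consuming 2,4-dienoyl-CoA reductase steps of even-numbered double
#' bonds are deliberately not modelled; see the package vignette.
#'
#' @param fa A [fatty_acid()] record.
#' @return List of class `"beta_oxidation"` with integer fields
#'   `acetyl_coa`, `nadh`, `fadh2`, `cycles`.
#' @export
fa_beta_oxidation_stoichiometry <- function(fa) {
  stopifnot(inherits(fa, "fatty_acid"))
  cycles <- fa$carbons %/% 2L - 1L
  structure(list(acetyl_coa = fa$carbons %/% 2L,
                 nadh = cycles,
                 fadh2 = cycles - fa$double_bonds,
                 cycles = cycles),
            class = "beta_oxidation")
}

# "C16:0" -> "160", "C22:6" -> "226"; used in reaction/metabolite ids.
fa_code <- function(label) gsub("[^0-9]", "", label)

# id of the lumped matrix beta-oxidation reaction for a species label
faox_id <- function(label) paste0("FAOXC", fa_code(label))

# id of the luminal uniform-TAG exchange for a species label
tag_exchange_id <- function(label) paste0("EX_tag", fa_code(label), "_u")

#' Molar mass of the uniform triacylglyceride of a fatty acid
#'
#' Diets supply each fatty-acid species as a TAG of three identical acyl
#' chains: `3 * MW(FA) + MW(glycerol) - 3 * MW(water)`.
#'
#' @param fa A [fatty_acid()] record.
#' @return Molar mass in g/mol.
#' @export
tag_molar_mass <- function(fa) 3 * fa$molar_mass + 92.09 - 3 * 18.02
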