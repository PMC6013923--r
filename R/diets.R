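#' Create a diet specification
#'
#' @param name Diet name (e.g. `"FISH0"`, `"FAT45"`).
#' @param lipid_frac,carb_frac,protein_frac Macronutrient mass fractions in
#'   g per g diet, each in `[0, 1]` and jointly summing to at most 1.
#' @param energy_density Energy density in kJ/g.
#' @param fa_profile Named numeric vector, g of each fatty-acid species per
#'   100 g dietary lipid (labels as in [builtin_fatty_acids()]); non-negative
#'   and summing to at most 100.
#' @param glucose_content Glucose derivable from the carbohydrate fraction,
#'   g per 100 g diet.
#' @return A list of class `"diet_spec"`.
#' @export
diet_spec <- function(name, lipid_frac, carb_frac, protein_frac,
                      energy_density, fa_profile, glucose_content) {
  fracs <- c(lipid = lipid_frac, carb = carb_frac, protein = protein_frac)
  if (any(fracs < 0 | fracs > 1)) {
    stop("diet '", name, "': macronutrient fractions must lie in [0, 1]")
  }
  if (sum(fracs) > 1 + 1e-9) {
    stop("diet '", name, "': macronutrient fractions sum to more than 1")
  }
  if (any(fa_profile < 0)) {
    stop("diet '", name, "': fatty-acid profile values must be non-negative")
  }
  if (sum(fa_profile) > 100 + 1e-9) {
    stop("diet '", name, "': fatty-acid profile sums to more than 100 g/100 g")
  }
  if (glucose_content < 0 || glucose_content > 100) {
    stop("diet '", name, "': glucose_content must lie in [0, 100]")
  }
  structure(list(name = name, lipid_frac = lipid_frac, carb_frac = carb_frac,
                 protein_frac = protein_frac, energy_density = energy_density,
                 fa_profile = fa_profile, glucose_content = glucose_content),
            class = "diet_spec")
}

#' The seven printed experimental diets
#'
#' Transcription of the printed composition table for the two mouse
#' feeding studies: three isocaloric high-fat diets differing in marine
#' fatty-acid (fish-oil) fraction (FISH0, FISH15, FISH44) and four diets of
#' increasing lipid/carbohydrate ratio (FAT10, FAT20, FAT30, FAT45, fat
#' energy% in the name). Macronutrients are wt%, the fatty-acid profile is
#' g per 100 g dietary lipid, and glucose is g derivable per 100 g diet.
#'
#' @return Named list of [diet_spec()] objects.
#' @export
builtin_diets <- function() {
  fa <- function(c140, c160, c180, c181, c182, c183, c205 = 0, c226 = 0) {
    c("C14:0" = c140, "C16:0" = c160, "C18:0" = c180, "C18:1" = c181,
      "C18:2" = c182, "C18:3" = c183, "C20:5" = c205, "C22:6" = c226)
  }
  diets <- list(
    diet_spec("FISH0", 0.352, 0.354, 0.205, 22.8,
              fa(2.4, 11.3, 3.7, 50.8, 19.4, 4.1, 0.2, 0.9), 31.3),
    diet_spec("FISH15", 0.352, 0.354, 0.205, 22.8,
              fa(2.4, 10.8, 3.7, 42.3, 16.6, 3.3, 1.3, 10.5), 31.3),
    diet_spec("FISH44", 0.352, 0.354, 0.205, 22.8,
              fa(2.4, 9.8, 4.2, 25.9, 11.1, 1.9, 3.3, 29.2), 31.3),
    diet_spec("FAT10", 0.043, 0.664, 0.190, 16.1,
              fa(0.9, 24.5, 4.0, 30.6, 35.2, 4.2), 65.3),
    diet_spec("FAT20", 0.090, 0.599, 0.200, 17.0,
              fa(1.5, 33.8, 4.0, 35.8, 22.6, 2.1), 57.7),
    diet_spec("FAT30", 0.143, 0.528, 0.212, 18.0,
              fa(1.6, 36.7, 4.0, 37.5, 18.6, 1.4), 49.2),
    diet_spec("FAT45", 0.236, 0.403, 0.233, 19.8,
              fa(1.8, 39.0, 4.0, 38.8, 15.4, 0.9), 34.4)
  )
  stats::setNames(diets, vapply(diets, `[[`, "", "name"))
}

#' Physiology parameters for the uptake-bound conversion
#'
#' @param food_intake Food intake in g diet per mouse per day.
#' @param intestinal_dry_mass Dry mass of the small-intestinal tissue pool
#'   the fluxes are normalized to, in g.
#' @param absorption_fraction Fraction of ingested nutrient reaching the
#'   enterocytes, in `(0, 1]`.
#' @param hours_per_day Hours over which daily intake is spread (24).
#' @return A list of class `"physiology_params"`.
#' @export
physiology_params <- function(food_intake,
                              intestinal_dry_mass = 0.25,
                              absorption_fraction = 1.0,
                              hours_per_day = 24) {
  vals <- c(food_intake = food_intake,
            intestinal_dry_mass = intestinal_dry_mass,
            absorption_fraction = absorption_fraction,
            hours_per_day = hours_per_day)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("physiology parameters must all be strictly positive")
  }
  if (absorption_fraction > 1) {
    stop("absorption_fraction must lie in (0, 1]")
  }
  structure(as.list(vals), class = "physiology_params")
}

#' Default physiology parameters for a builtin diet
#'
#' The feeding studies report intake only in their original publications;
#' these defaults are package assumptions, documented in the vignette:
#' 2.5 g/day for the (energy-dense) fish-oil diets, 4.0 g/day for the
#' lipid/carbohydrate series, 0.25 g intestinal dry mass, complete
#' absorption. Publication-grade runs should supply measured values.
#'
#' @param diet_name Diet name, used to pick the intake default.
#' @return A [physiology_params()] object.
#' @export
default_physiology <- function(diet_name) {
  physiology_params(food_intake = if (grepl("^FISH", diet_name)) 2.5 else 4.0)
}

MW_GLUCOSE <- 180.16
MW_GLYCEROL <- 92.09
MW_WATER <- 18.02

#' Convert a diet composition into exchange-reaction uptake bounds
#'
#' Each fatty-acid species `f` with profile `p_f` (g per 100 g lipid)
#' contributes `food_intake * lipid_frac * p_f / 100` grams of uniform TAG
#' per day; divided by the TAG molar mass (`3 MW_f + MW_glycerol -
#' 3 MW_water`), scaled by the absorption fraction and normalized by
#' intestinal dry mass and hours per day, this gives an uptake ceiling in
#' mmol per g dry tissue per hour. Glucose is converted analogously from
#' `glucose_content` (g per 100 g diet) with MW 180.16 g/mol.
#'
#' @param diet A [diet_spec()].
#' @param phys A [physiology_params()].
#' @return An object of class `"uptake_bounds"`: named numeric vector
#'   `bounds` (stored positive; applied as negative lower bounds on the
#'   `EX_` reactions) with one glucose entry plus one entry per
#'   nonzero-profile fatty acid, and the `diet` name.
#' @export
compute_uptake_bounds <- function(diet, phys = default_physiology(diet$name)) {
  stopifnot(inherits(diet, "diet_spec"), inherits(phys, "physiology_params"))
  fas <- builtin_fatty_acids()
  unknown <- setdiff(names(diet$fa_profile)[diet$fa_profile > 0], names(fas))
  if (length(unknown)) {
    stop("no molar mass on record for fatty acid(s) ",
         paste(unknown, collapse = ", "), "; known species: ",
         paste(names(fas), collapse = ", "))
  }
  per_mmol <- function(grams_per_day, mw) {
    phys$absorption_fraction * (grams_per_day / mw * 1000) /
      (phys$intestinal_dry_mass * phys$hours_per_day)
  }
  bounds <- c(EX_glc__D_u = per_mmol(
    phys$food_intake * diet$glucose_content / 100, MW_GLUCOSE))
  for (lab in names(diet$fa_profile)) {
    p <- diet$fa_profile[[lab]]
    if (p <= 0) next
    grams <- phys$food_intake * diet$lipid_frac * p / 100
    bounds[[tag_exchange_id(lab)]] <- per_mmol(grams, tag_molar_mass(fas[[lab]]))
  }
  structure(list(diet = diet$name, bounds = bounds, physiology = phys),
            class = "uptake_bounds")
}

#' @export
print.uptake_bounds <- function(x, ...) {
  cat("Uptake bounds for diet ", x$diet, " (mmol g-1 h-1):\n", sep = "")
  print(round(x$bounds, 6))
  invisible(x)
}

#' Apply diet-derived uptake bounds to a model
#'
#' Each named exchange reaction gets `lower_bound = -bound` (uptake allowed
#' up to the diet-derived ceiling; these are maximal potential intake rates,
#' not forced uptakes). With `closed_default = TRUE` every other substrate
#' exchange is closed to uptake (`lower_bound = 0`) while the oxygen, water,
#' phosphate and proton exchanges remain fully open; secretion is untouched
#' everywhere.
#'
#' @param model A `"metabolic_model"`.
#' @param ub An `"uptake_bounds"` object (or named numeric vector of
#'   positive uptake ceilings keyed by exchange-reaction id).
#' @param closed_default Close uptake on unnamed substrate exchanges.
#' @return The constrained model, with the diet name attached as
#'   `model$diet`.
#' @export
apply_diet <- function(model, ub, closed_default = TRUE) {
  bounds <- if (inherits(ub, "uptake_bounds")) ub$bounds else ub
  if (any(bounds < 0)) stop("uptake bounds must be stored non-negative")
  rxn_ids <- reaction_ids(model)
  missing <- setdiff(names(bounds), rxn_ids)
  if (length(missing)) {
    stop("model '", model$id, "' lacks exchange reaction(s): ",
         paste(missing, collapse = ", "))
  }
  if (closed_default) {
    keep_open <- c("EX_o2_u", "EX_h2o_u", "EX_pi_u", "EX_h_u")
    other_ex <- setdiff(rxn_ids[is_exchange(model)],
                        c(names(bounds), keep_open))
    model <- set_bounds(model, other_ex, lower = 0)
  }
  model <- set_bounds(model, names(bounds), lower = -unname(bounds))
  model$diet <- if (inherits(ub, "uptake_bounds")) ub$diet else NULL
  model
}
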