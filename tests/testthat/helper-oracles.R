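# Independent oracles for the fixture's energetics, kept deliberately free
# of the package's LP and model-construction code paths.

# Cycle-by-cycle enumeration of beta-oxidation intermediates: each cycle
# shortens the acyl chain by two carbons and reduces one NAD+; the
# FAD-dependent dehydrogenation is skipped while pre-existing double bonds
# remain (one is consumed instead).
beta_ox_enumerate <- function(carbons, double_bonds) {
  stopifnot(carbons %% 2 == 0, carbons >= 4)
  acetyl <- 0L; nadh <- 0L; fadh2 <- 0L; cycles <- 0L
  c_now <- carbons; d_now <- double_bonds
  while (c_now > 2) {
    cycles <- cycles + 1L
    if (d_now > 0) d_now <- d_now - 1L else fadh2 <- fadh2 + 1L
    nadh <- nadh + 1L
    c_now <- c_now - 2L
    acetyl <- acetyl + 1L
  }
  acetyl <- acetyl + 1L   # the terminal acetyl-CoA
  list(acetyl_coa = acetyl, nadh = nadh, fadh2 = fadh2, cycles = cycles)
}

# Proton-ledger closed forms for maximal ATP yield. Cofactor and matrix
# chemical-proton budgets are tallied per substrate, then the synthase flux
# A is fixed by the matrix proton balance:
#   ha * A = (hn + 1) * NADH_m + hf * FADH2_m - H_m^chem
# and total ATP = substrate-level ATP + A. Routes assumed (the network's
# optimum): cytosolic NADH enters via the malate-aspartate shuttle, glycerol
# is oxidized via glycerol kinase and the cytosolic NAD-linked
# glycerol-3-phosphate dehydrogenase.
oracle_atp_per_glucose <- function(hn = 10, hf = 6, ha = 4) {
  nadh <- 10            # 2 glycolysis (via shuttle) + 2 PDH + 6 TCA
  fadh2 <- 2            # succinate dehydrogenase
  slp <- 4              # 2 glycolysis + 2 succinyl-CoA synthetase
  h_chem <- 12          # 2 PYRt + 2 PDH + 2 ICDH + 2 AKGD + 2 MDH + 2 PIt
  slp + ((hn + 1) * nadh + hf * fadh2 - h_chem) / ha
}

# per mole of the uniform TAG of a Cn:d fatty acid (3 identical chains +
# glycerol); activation costs 2 ATP per chain (AMP + PPi route)
oracle_atp_per_tag <- function(carbons, double_bonds, hn = 10, hf = 6, ha = 4) {
  y <- carbons / 2 - 1          # beta-oxidation cycles per chain
  a <- carbons / 2              # acetyl-CoA per chain
  nadh_fa <- y + 3 * a
  fadh2_fa <- (y - double_bonds) + a
  slp_fa <- a - 2
  h_fa <- y + 4 * a             # beta-ox + (ICDH+AKGD+MDH+PIt) per acetyl
  # glycerol: kinase -1 ATP; 2 cytosolic NADH (G3P dehydrogenase + lower
  # glycolysis); +2 ATP lower glycolysis; then pyruvate -> full oxidation
  nadh_gl <- 2 + 1 + 3
  fadh2_gl <- 1
  slp_gl <- -1 + 2 + 1
  h_gl <- 1 + 1 + 3 + 1         # PYRt + PDH + (ICDH,AKGD,MDH) + PIt
  nadh <- 3 * nadh_fa + nadh_gl
  fadh2 <- 3 * fadh2_fa + fadh2_gl
  slp <- 3 * slp_fa + slp_gl
  h_chem <- 3 * h_fa + h_gl
  slp + ((hn + 1) * nadh + hf * fadh2 - h_chem) / ha
}

# independent LP oracle: scipy.optimize.linprog (HiGHS) through the
# system python; returns the maximal objective value
scipy_fba_objective <- function(model) {
  S <- stoichiometric_matrix(model, sparse = FALSE)
  payload <- list(
    S = unname(as.matrix(S)),
    lb = unname(lower_bounds(model)),
    ub = unname(upper_bounds(model)),
    obj = as.numeric(reaction_ids(model) == model$objective_reaction))
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, fin, digits = NA)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    sprintf("d = json.load(open(%s))", deparse(fin)),
    "S = np.array(d['S'], dtype=float)",
    "res = linprog(-np.array(d['obj'], dtype=float), A_eq=S,",
    "              b_eq=np.zeros(S.shape[0]),",
    "              bounds=list(zip(d['lb'], d['ub'])), method='highs')",
    "json.dump({'status': int(res.status), 'objective': -res.fun},",
    sprintf("          open(%s, 'w'))", deparse(fout))
  ), script)
  status <- system2("python", script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) {
    stop("python LP oracle failed: ", paste(status, collapse = "\n"))
  }
  res <- jsonlite::fromJSON(fout)
  if (res$status != 0) stop("python LP oracle returned status ", res$status)
  res$objective
}

# quantile oracle: manual type-7 linear interpolation on a sorted copy
quantile7_oracle <- function(x, p) {
  xs <- sort(x); n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}
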