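# Small models built in code, shared across test files.

# EX_A -> A -> B -> EX_B, uptake of A limited to `cap`
chain_model <- function(cap = 1) {
  metabolic_model(
    metabolites = list(metabolite("A_c"), metabolite("B_c")),
    reactions = list(
      reaction("EX_A_c", c(A_c = -1), lower_bound = -cap, upper_bound = 1000),
      reaction("R1", c(A_c = -1, B_c = 1), lower_bound = 0),
      reaction("EX_B_c", c(B_c = -1), lower_bound = 0)),
    objective_reaction = "EX_B_c",
    id = "chain")
}

# segment polytope: v(EX) = v(DM) in [0, 1]
segment_model <- function() {
  metabolic_model(
    metabolites = list(metabolite("A_c")),
    reactions = list(
      reaction("SRC", c(A_c = 1), lower_bound = 0, upper_bound = 1),
      reaction("SNK", c(A_c = -1), lower_bound = 0, upper_bound = 1000)),
    objective_reaction = "SNK",
    id = "segment")
}

# two bounded sources feeding one capped sink:
# feasible set {(v1, v2) in [0,1]^2 : v1 + v2 <= 1.5}, v3 = v1 + v2
toy_polytope_model <- function() {
  metabolic_model(
    metabolites = list(metabolite("A_c")),
    reactions = list(
      reaction("SRC1", c(A_c = 1), lower_bound = 0, upper_bound = 1),
      reaction("SRC2", c(A_c = 1), lower_bound = 0, upper_bound = 1),
      reaction("SNK", c(A_c = -1), lower_bound = 0, upper_bound = 1.5)),
    objective_reaction = "SNK",
    id = "toy_polytope")
}

# rejection sampler over the toy polytope (independent of the ACHR code)
toy_polytope_rejection <- function(n, seed) {
  withr::with_seed(seed, {
    out <- matrix(NA_real_, 2, 0)
    while (ncol(out) < n) {
      cand <- matrix(stats::runif(2 * n), 2)
      keep <- colSums(cand) <= 1.5
      out <- cbind(out, cand[, keep, drop = FALSE])
    }
    out <- out[, seq_len(n), drop = FALSE]
    rbind(out, colSums(out))   # rows: SRC1, SRC2, SNK
  })
}

# random small connected-ish models for property tests
random_small_model <- function(seed, n_mets = 5, n_rxns = 8) {
  withr::with_seed(seed, {
    met_ids <- paste0("m", seq_len(n_mets), "_c")
    mets <- lapply(met_ids, metabolite)
    rxns <- vector("list", n_rxns)
    for (k in seq_len(n_rxns)) {
      sz <- sample(1:3, 1)
      who <- sample(met_ids, sz)
      coef <- sample(c(-2, -1, 1, 2), sz, replace = TRUE)
      rev <- stats::runif(1) < 0.4
      rxns[[k]] <- reaction(paste0("r", k), stats::setNames(coef, who),
                            lower_bound = if (rev) -10 else 0,
                            upper_bound = 10)
    }
    metabolic_model(mets, rxns, objective_reaction = NULL,
                    id = paste0("rand", seed))
  })
}

# brute-force dead-end oracle: explicit producer/consumer sets per metabolite
dead_ends_bruteforce <- function(model) {
  out <- character()
  for (met in model$metabolites) {
    producers <- consumers <- 0L
    for (r in model$reactions) {
      s <- r$stoichiometry[met$id]
      if (is.na(s)) next
      fwd <- r$upper_bound > 0; rev <- r$lower_bound < 0
      if ((s > 0 && fwd) || (s < 0 && rev)) producers <- producers + 1L
      if ((s < 0 && fwd) || (s > 0 && rev)) consumers <- consumers + 1L
    }
    if (producers == 0L || consumers == 0L) out <- c(out, met$id)
  }
  out
}
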