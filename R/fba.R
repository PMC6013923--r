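#' Flux balance analysis with maximal ATP production as objective
#'
#' Maximizes flux through the model's objective reaction (the cytosolic ATP
#' demand in the shipped fixture) subject to steady state (`S v = 0`) and the
#' flux bounds. Degenerate optima are common in these networks: only
#' `objective_value` is contract-stable, the returned flux vector is one
#' optimal vertex among possibly many.
#'
#' @param model A `"metabolic_model"` with an objective reaction.
#' @param tolerance Residual tolerance used when reporting steady-state
#'   validity of the returned solution.
#' @return An object of class `"flux_solution"`: `objective_value`, named
#'   `fluxes`, `status` (`"optimal"`, `"infeasible"`, or
#'   `"iteration-limit"`), and the achieved `residual` (max |S v|).
#' @export
fba_max_atp <- function(model, tolerance = 1e-6) {
  validate_model(model)
  if (is.null(model$objective_reaction)) {
    stop("model '", model$id, "' has no objective reaction")
  }
  rxn_ids <- reaction_ids(model)
  obj <- as.numeric(rxn_ids == model$objective_reaction)
  S <- stoichiometric_matrix(model, sparse = FALSE)
  sol <- solve_lp(obj, S, lower_bounds(model), upper_bounds(model),
                  maximize = TRUE)
  residual <- if (sol$status == "optimal") {
    max(abs(S %*% sol$fluxes))
  } else NA_real_
  structure(
    list(objective_value = if (sol$status == "optimal") sol$objective else NA_real_,
         fluxes = sol$fluxes,
         status = sol$status,
         objective_reaction = model$objective_reaction,
         residual = residual,
         tolerance = tolerance),
    class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("Flux balance solution (", x$status, ")\n", sep = "")
  if (x$status == "optimal") {
    cat("  objective ", x$objective_reaction, " = ",
        format(x$objective_value, digits = 8),
        " mmol g-1 h-1  (max |S v| = ", format(x$residual, digits = 3),
        ")\n", sep = "")
  }
  invisible(x)
}

# model with every exchange reaction opened to [-bound, bound]
open_all_exchanges <- function(model, bound = NULL) {
  if (is.null(bound)) {
    bound <- max(1000, abs(lower_bounds(model)), abs(upper_bounds(model)))
  }
  ex_ids <- reaction_ids(model)[is_exchange(model)]
  set_bounds(model, ex_ids, lower = -bound, upper = bound)
}

#' Model integrity report
#'
#' Reproduces the two standard consistency checks for a freshly built
#' network: with every exchange reaction opened, (i) the model must be able
#' to produce ATP (flux-balance objective above `tolerance`), and (ii) there
#' must be no dead-end metabolites. Reactions unable to carry any flux
#' (max |v| below `tolerance` in both directions) are reported as blocked;
#' reactions whose bounds pin them to zero are blocked by construction.
#'
#' @param model A `"metabolic_model"`.
#' @param tolerance Flux threshold below which a reaction counts as blocked.
#' @return A list of class `"integrity_report"` with fields `atp_producible`,
#'   `max_atp`, `dead_ends`, `blocked_reactions`.
#' @export
check_model_integrity <- function(model, tolerance = 1e-6) {
  open <- open_all_exchanges(model)
  sol <- fba_max_atp(open, tolerance = tolerance)
  atp <- sol$status == "optimal" && sol$objective_value > tolerance

  rxn_ids <- reaction_ids(open)
  lb <- lower_bounds(open); ub <- upper_bounds(open)
  S <- stoichiometric_matrix(open, sparse = FALSE)
  unblocked <- rep(FALSE, length(rxn_ids))
  unblocked[abs(sol$fluxes) > tolerance] <- TRUE
  unblocked[lb == 0 & ub == 0] <- NA   # pinned shut: blocked by bounds

  # a few random-objective solves knock out most candidates cheaply, then
  # per-reaction max/min LPs settle the remainder
  withr::with_seed(20180615, {
    for (k in 1:4) {
      r <- solve_lp(stats::rnorm(length(rxn_ids)), S, lb, ub)
      if (r$status == "optimal") unblocked[abs(r$fluxes) > tolerance] <- TRUE
    }
  })
  for (j in which(!unblocked & !is.na(unblocked))) {
    e <- as.numeric(seq_along(rxn_ids) == j)
    hi <- solve_lp(e, S, lb, ub, maximize = TRUE)
    if (hi$status == "optimal" && hi$objective > tolerance) {
      unblocked[abs(hi$fluxes) > tolerance] <- TRUE
      next
    }
    lo <- solve_lp(e, S, lb, ub, maximize = FALSE)
    if (lo$status == "optimal" && lo$objective < -tolerance) {
      unblocked[abs(lo$fluxes) > tolerance] <- TRUE
    }
  }
  blocked <- rxn_ids[is.na(unblocked) | !unblocked]

  structure(
    list(atp_producible = atp,
         max_atp = sol$objective_value,
         dead_ends = find_dead_end_metabolites(model),
         blocked_reactions = blocked),
    class = "integrity_report")
}

#' @export
print.integrity_report <- function(x, ...) {
  cat("Model integrity:\n")
  cat("  ATP producible: ", x$atp_producible,
      " (max ", format(x$max_atp, digits = 6), ")\n", sep = "")
  cat("  dead-end metabolites: ",
      if (length(x$dead_ends)) paste(x$dead_ends, collapse = ", ") else "none",
      "\n", sep = "")
  cat("  blocked reactions: ",
      if (length(x$blocked_reactions))
        paste(x$blocked_reactions, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to steady state, the flux
#' bounds, and (for `fraction_of_optimum > 0`) the optimality constraint
#' `objective >= fraction_of_optimum * optimum`.
#'
#' @param model A feasible `"metabolic_model"`.
#' @param fraction_of_optimum Number in `[0, 1]`.
#' @param reactions Reaction ids to analyze (default: all).
#' @return Data frame with columns `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, fraction_of_optimum = 0,
                             reactions = reaction_ids(model)) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  rxn_ids <- reaction_ids(model)
  idx <- match(reactions, rxn_ids)
  if (anyNA(idx)) {
    stop("unknown reaction(s): ", paste(reactions[is.na(idx)], collapse = ", "))
  }
  S <- stoichiometric_matrix(model, sparse = FALSE)
  lb <- lower_bounds(model); ub <- upper_bounds(model)

  ineq_A <- NULL; ineq_b <- NULL
  if (fraction_of_optimum > 0) {
    sol <- fba_max_atp(model)
    if (sol$status != "optimal") stop("model is ", sol$status,
                                      "; cannot constrain to optimality")
    ineq_A <- matrix(as.numeric(rxn_ids == model$objective_reaction), 1)
    ineq_b <- fraction_of_optimum * sol$objective_value
  }

  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_)
  for (k in seq_along(idx)) {
    e <- as.numeric(seq_along(rxn_ids) == idx[k])
    lo <- solve_lp(e, S, lb, ub, maximize = FALSE,
                   ineq_A = ineq_A, ineq_b = ineq_b)
    hi <- solve_lp(e, S, lb, ub, maximize = TRUE,
                   ineq_A = ineq_A, ineq_b = ineq_b)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("flux variability subproblem for '", reactions[k], "' was ",
           if (lo$status != "optimal") lo$status else hi$status)
    }
    out$min[k] <- lo$objective
    out$max[k] <- hi$objective
  }
  out
}
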