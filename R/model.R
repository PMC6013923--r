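#' Compartments used by enterocyte mitochondrial models
#'
#' Models distinguish three compartments: luminal `"u"`, cytosolic `"c"`
#' (which also stands for the mitochondrial intermembrane space, since the
#' outer membrane is freely permeable to small metabolites), and the
#' mitochondrial matrix `"m"`.
#'
#' @return Character vector of valid compartment tags.
#' @export
compartments <- function() c("u", "c", "m")

#' Create a metabolite record
#'
#' Metabolite identifiers follow the BiGG convention of a trailing
#' underscore-separated compartment tag (e.g. `"glc__D_u"` for luminal
#' D-glucose).
#'
#' @param id Metabolite identifier; its trailing tag must equal `compartment`.
#' @param name Human-readable name.
#' @param compartment One of `"u"`, `"c"`, `"m"`. If missing, inferred from
#'   the trailing tag of `id`.
#' @param formula Optional elemental composition string such as `"C6H12O6"`.
#' @param charge Optional integer formal charge.
#' @return A list of class `"metabolite"`.
#' @export
metabolite <- function(id, name = id, compartment = NULL,
                       formula = NULL, charge = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  tag <- sub("^.*_([a-z])$", "\\1", id)
  if (is.null(compartment)) compartment <- tag
  if (!compartment %in% compartments()) {
    stop("unknown compartment tag '", compartment, "' for metabolite '", id, "'")
  }
  if (tag != compartment) {
    stop("metabolite id '", id, "' does not end in compartment tag '_",
         compartment, "'")
  }
  structure(
    list(id = id, name = name, compartment = compartment,
         formula = formula, charge = charge),
    class = "metabolite"
  )
}

#' Create a reaction record
#'
#' @param id Reaction identifier (BiGG style, e.g. `"PDHm"`, `"EX_glc__D_u"`).
#' @param stoichiometry Named numeric vector mapping metabolite ids to signed
#'   coefficients; negative coefficients are consumed, positive produced.
#'   Zero coefficients are not allowed.
#' @param name Human-readable name.
#' @param lower_bound,upper_bound Flux bounds in mmol per g dry intestinal
#'   tissue per hour. Reversibility is encoded solely as `lower_bound < 0`.
#' @param gene_rule Boolean gene association over gene symbols using
#'   `and`/`or` (case-insensitive) and parentheses; `""` when unknown.
#' @param subsystem Free-text pathway label.
#' @return A list of class `"reaction"`.
#' @export
reaction <- function(id, stoichiometry, name = id,
                     lower_bound = -1000, upper_bound = 1000,
                     gene_rule = "", subsystem = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  s <- unlist(stoichiometry)
  storage.mode(s) <- "double"
  if (is.null(names(s)) || any(!nzchar(names(s)))) {
    stop("reaction '", id, "': stoichiometry must be a named numeric vector")
  }
  if (anyDuplicated(names(s))) {
    stop("reaction '", id, "': duplicated metabolite in stoichiometry")
  }
  if (any(s == 0)) {
    stop("reaction '", id, "': zero stoichiometric coefficients are not allowed")
  }
  if (lower_bound > upper_bound) {
    stop("reaction '", id, "': lower_bound exceeds upper_bound")
  }
  structure(
    list(id = id, name = name, stoichiometry = s,
         lower_bound = as.numeric(lower_bound),
         upper_bound = as.numeric(upper_bound),
         gene_rule = gene_rule, subsystem = subsystem),
    class = "reaction"
  )
}

#' Assemble a compartmentalized constraint-based metabolic model
#'
#' The model is the carrier of the stoichiometric matrix `S` and the flux
#' bounds used by [fba_max_atp()] and [achr_sample()]. Gene ids are the union
#' of symbols appearing in the reactions' gene rules.
#'
#' @param metabolites List of [metabolite()] records.
#' @param reactions List of [reaction()] records.
#' @param objective_reaction Id of the reaction maximized by flux balance
#'   analysis (the ATP demand reaction in the shipped fixture).
#' @param id Model identifier string.
#' @return An object of class `"metabolic_model"`.
#' @export
metabolic_model <- function(metabolites, reactions, objective_reaction,
                            id = "model") {
  m <- structure(
    list(id = id,
         metabolites = metabolites,
         reactions = reactions,
         genes = sort(unique(unlist(lapply(reactions, function(r)
           parse_gene_ids(r$gene_rule))))),
         objective_reaction = objective_reaction),
    class = "metabolic_model"
  )
  validate_model(m)
  m
}

# Gene symbols in a rule: tokens that are not the boolean connectives.
parse_gene_ids <- function(rule) {
  if (is.null(rule) || !nzchar(rule)) return(character())
  toks <- strsplit(gsub("[()]", " ", rule), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  toks[!tolower(toks) %in% c("and", "or")]
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique metabolite and reaction ids,
#' compartment tags consistent with declared compartments, all stoichiometry
#' references resolvable, no zero coefficients, and ordered bounds.
#'
#' @param model A `"metabolic_model"`.
#' @return The model, invisibly; errors describe the first violation found.
#' @export
validate_model <- function(model) {
  met_ids <- vapply(model$metabolites, `[[`, "", "id")
  rxn_ids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(met_ids)) {
    stop("duplicated metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  }
  if (anyDuplicated(rxn_ids)) {
    stop("duplicated reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  }
  for (met in model$metabolites) {
    if (!met$compartment %in% compartments()) {
      stop("metabolite '", met$id, "': unknown compartment '",
           met$compartment, "'")
    }
  }
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoichiometry), met_ids)
    if (length(missing)) {
      stop("reaction '", r$id, "' references undeclared metabolite(s): ",
           paste(missing, collapse = ", "))
    }
    if (r$lower_bound > r$upper_bound) {
      stop("reaction '", r$id, "': lower_bound exceeds upper_bound")
    }
  }
  if (!is.null(model$objective_reaction) &&
      !model$objective_reaction %in% rxn_ids) {
    stop("objective reaction '", model$objective_reaction,
         "' is not in the model")
  }
  invisible(model)
}

#' Ids of the metabolites / reactions of a model
#' @param model A `"metabolic_model"`.
#' @return Character vector in model order.
#' @export
metabolite_ids <- function(model) vapply(model$metabolites, `[[`, "", "id")

#' @rdname metabolite_ids
#' @export
reaction_ids <- function(model) vapply(model$reactions, `[[`, "", "id")

#' Stoichiometric matrix of a model
#'
#' @param model A `"metabolic_model"`.
#' @param sparse Return a `Matrix::sparseMatrix` (default) or a dense matrix.
#' @return Matrix `S` with one row per metabolite and one column per reaction;
#'   `S[i, j]` is the coefficient of metabolite `i` in reaction `j`, 0 when
#'   absent. Dimnames carry the ids.
#' @export
stoichiometric_matrix <- function(model, sparse = TRUE) {
  met_ids <- metabolite_ids(model)
  rxn_ids <- reaction_ids(model)
  i <- integer(); j <- integer(); x <- numeric()
  for (k in seq_along(model$reactions)) {
    s <- model$reactions[[k]]$stoichiometry
    i <- c(i, match(names(s), met_ids))
    j <- c(j, rep.int(k, length(s)))
    x <- c(x, unname(s))
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(met_ids), length(rxn_ids)),
                            dimnames = list(met_ids, rxn_ids))
  if (sparse) S else as.matrix(S)
}

#' Lower / upper flux bounds of a model
#' @param model A `"metabolic_model"`.
#' @return Named numeric vector in reaction order.
#' @export
lower_bounds <- function(model) {
  stats::setNames(vapply(model$reactions, `[[`, 0, "lower_bound"),
                  reaction_ids(model))
}

#' @rdname lower_bounds
#' @export
upper_bounds <- function(model) {
  stats::setNames(vapply(model$reactions, `[[`, 0, "upper_bound"),
                  reaction_ids(model))
}

#' Is a reaction an exchange (boundary) reaction?
#'
#' An exchange reaction touches exactly one metabolite, adding it to or
#' removing it from the system; by the BiGG sign convention uptake is a
#' negative flux on a reaction written `met_u <=>`.
#'
#' @param model A `"metabolic_model"`.
#' @return Named logical vector in reaction order.
#' @export
is_exchange <- function(model) {
  stats::setNames(
    vapply(model$reactions, function(r) length(r$stoichiometry) == 1L, TRUE),
    reaction_ids(model))
}

#' Find dead-end metabolites
#'
#' A dead-end metabolite can only be produced or only consumed, which forces
#' zero steady-state flux through all its reactions. A reversible reaction
#' (one with `lower_bound < 0`) counts as both a producer and a consumer of
#' every participant; exchange reactions likewise connect their metabolite to
#' the boundary in whichever directions their bounds allow.
#'
#' @param model A `"metabolic_model"`.
#' @return Character vector of dead-end metabolite ids (possibly empty).
#' @export
find_dead_end_metabolites <- function(model) {
  met_ids <- metabolite_ids(model)
  produced <- stats::setNames(logical(length(met_ids)), met_ids)
  consumed <- produced
  for (r in model$reactions) {
    fwd <- r$upper_bound > 0
    rev <- r$lower_bound < 0
    s <- r$stoichiometry
    prod_ids <- names(s)[(s > 0 & fwd) | (s < 0 & rev)]
    cons_ids <- names(s)[(s < 0 & fwd) | (s > 0 & rev)]
    produced[prod_ids] <- TRUE
    consumed[cons_ids] <- TRUE
  }
  met_ids[!(produced & consumed)]
}

#' Classify reactions by compartment and role
#'
#' Each reaction is assigned exactly one class: `exchange` (boundary reaction
#' touching a single metabolite), `transport` (non-exchange reaction whose
#' metabolites span at least two compartments), or the single compartment of
#' its metabolites (`luminal`, `cytosolic`, `mitochondrial`).
#'
#' @param model A `"metabolic_model"`.
#' @return A list of class `"reaction_classification"` with `counts` (named
#'   integer vector over the five classes) and `assignment` (named character
#'   vector, one class per reaction).
#' @export
classify_reactions <- function(model) {
  met_comp <- stats::setNames(
    vapply(model$metabolites, `[[`, "", "compartment"), metabolite_ids(model))
  comp_name <- c(u = "luminal", c = "cytosolic", m = "mitochondrial")
  assignment <- vapply(model$reactions, function(r) {
    if (length(r$stoichiometry) == 1L) return("exchange")
    comps <- unique(met_comp[names(r$stoichiometry)])
    if (length(comps) > 1L) "transport" else comp_name[[comps]]
  }, "")
  names(assignment) <- reaction_ids(model)
  classes <- c("luminal", "cytosolic", "mitochondrial", "transport", "exchange")
  counts <- stats::setNames(integer(length(classes)), classes)
  tab <- table(assignment)
  counts[names(tab)] <- as.integer(tab)
  structure(list(counts = counts, assignment = assignment),
            class = "reaction_classification")
}

#' @export
print.reaction_classification <- function(x, ...) {
  cat("Reaction classification:\n")
  print(x$counts)
  invisible(x)
}

#' Retrieve a reaction by id
#' @param model A `"metabolic_model"`.
#' @param id Reaction id.
#' @return The `"reaction"` record.
#' @export
get_reaction <- function(model, id) {
  k <- match(id, reaction_ids(model))
  if (is.na(k)) stop("no reaction '", id, "' in model '", model$id, "'")
  model$reactions[[k]]
}

#' Set flux bounds on one or more reactions
#'
#' @param model A `"metabolic_model"`.
#' @param ids Reaction ids.
#' @param lower,upper Replacement bounds, recycled along `ids`; `NA` entries
#'   leave the corresponding bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, ids, lower = NA, upper = NA) {
  idx <- match(ids, reaction_ids(model))
  if (anyNA(idx)) {
    stop("no reaction(s) ", paste(ids[is.na(idx)], collapse = ", "),
         " in model '", model$id, "'")
  }
  lower <- rep_len(lower, length(idx))
  upper <- rep_len(upper, length(idx))
  for (k in seq_along(idx)) {
    r <- model$reactions[[idx[k]]]
    if (!is.na(lower[k])) r$lower_bound <- as.numeric(lower[k])
    if (!is.na(upper[k])) r$upper_bound <- as.numeric(upper[k])
    if (r$lower_bound > r$upper_bound) {
      stop("reaction '", r$id, "': lower_bound exceeds upper_bound")
    }
    model$reactions[[idx[k]]] <- r
  }
  model
}

#' Remove reactions (and optionally orphaned metabolites) from a model
#' @param model A `"metabolic_model"`.
#' @param ids Reaction ids to drop.
#' @param prune_metabolites Drop metabolites left without any reaction.
#' @return The reduced model.
#' @export
remove_reactions <- function(model, ids, prune_metabolites = FALSE) {
  keep <- !reaction_ids(model) %in% ids
  model$reactions <- model$reactions[keep]
  if (prune_metabolites) {
    used <- unique(unlist(lapply(model$reactions,
                                 function(r) names(r$stoichiometry))))
    model$metabolites <- model$metabolites[metabolite_ids(model) %in% used]
  }
  model$genes <- sort(unique(unlist(lapply(model$reactions, function(r)
    parse_gene_ids(r$gene_rule)))))
  if (!is.null(model$objective_reaction) &&
      !model$objective_reaction %in% reaction_ids(model)) {
    model$objective_reaction <- NULL
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model '", x$id, "'\n", sep = "")
  cat("  metabolites: ", length(x$metabolites),
      "  reactions: ", length(x$reactions),
      "  genes: ", length(x$genes), "\n", sep = "")
  if (!is.null(x$objective_reaction)) {
    cat("  objective: ", x$objective_reaction, "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  cls <- classify_reactions(object)
  comp <- table(vapply(object$metabolites, `[[`, "", "compartment"))
  out <- list(id = object$id,
              n_metabolites = length(object$metabolites),
              n_reactions = length(object$reactions),
              n_genes = length(object$genes),
              metabolites_by_compartment = comp,
              reaction_classes = cls$counts,
              dead_ends = find_dead_end_metabolites(object),
              objective = object$objective_reaction)
  class(out) <- "summary.metabolic_model"
  out
}

#' @export
print.summary.metabolic_model <- function(x, ...) {
  cat("Metabolic model '", x$id, "': ", x$n_metabolites, " metabolites, ",
      x$n_reactions, " reactions, ", x$n_genes, " genes\n", sep = "")
  cat("Metabolites by compartment:\n"); print(x$metabolites_by_compartment)
  cat("Reaction classes:\n"); print(x$reaction_classes)
  cat("Dead-end metabolites: ",
      if (length(x$dead_ends)) paste(x$dead_ends, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}
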