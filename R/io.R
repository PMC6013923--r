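#' Load a metabolic model from disk
#'
#' Three dialects are supported: the package's native JSON schema
#' (`"native-json"`), SBML Level 3 with the FBC extension (`"sbml"`), and a
#' tabular reaction-list dialect (`"tabular"`) matching common COBRA
#' spreadsheet exports: a header row followed by columns
#' `id`, `name`, `formula`, `lower_bound`, `upper_bound`, `gene_rule`,
#' `subsystem`, where `formula` is a reaction string using `-->` or `<=>`
#' arrows and `coef metabolite_id` terms.
#'
#' Foreign files that tag intermembrane-space metabolites with an `"i"`
#' compartment are mapped to cytosolic `"c"`, following the convention that
#' the outer mitochondrial membrane is freely permeable.
#'
#' @param path File path.
#' @param format One of `"native-json"`, `"sbml"`, `"tabular"`; by default
#'   guessed from the file extension (`.json`, `.xml`/`.sbml`, `.tsv`/`.txt`).
#' @return A validated `"metabolic_model"`.
#' @export
load_model <- function(path, format = c("auto", "native-json", "sbml", "tabular")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "native-json",
                     xml = , sbml = "sbml",
                     tsv = , txt = "tabular",
                     stop("cannot guess model format from extension of ", path))
  }
  switch(format,
         "native-json" = read_model_json(path),
         "sbml" = read_model_sbml(path),
         "tabular" = read_model_tabular(path))
}

#' Write a metabolic model to disk
#'
#' @param model A `"metabolic_model"`.
#' @param path Output file path.
#' @param format See [load_model()]. `"tabular"` writes the human-readable
#'   reaction table (which [load_model()] can read back, though metabolite
#'   names, formulas and charges are not representable in that dialect).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path,
                        format = c("auto", "native-json", "sbml", "tabular")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "native-json",
                     xml = , sbml = "sbml",
                     tsv = , txt = "tabular",
                     stop("cannot guess model format from extension of ", path))
  }
  switch(format,
         "native-json" = write_model_json(model, path),
         "sbml" = write_model_sbml(model, path),
         "tabular" = write_reaction_table(model, path))
  invisible(path)
}

## ---- native JSON ----------------------------------------------------------

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed JSON in ", path, ": ",
                                           conditionMessage(e)))
  for (key in c("metabolites", "reactions")) {
    if (is.null(doc[[key]])) stop("model JSON ", path, " lacks '", key, "'")
  }
  mets <- lapply(doc$metabolites, function(m) {
    metabolite(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = m$compartment,
               formula = m$formula, charge = m$charge)
  })
  rxns <- lapply(doc$reactions, function(r) {
    reaction(id = r$id,
             stoichiometry = unlist(r$stoichiometry),
             name = if (is.null(r$name)) r$id else r$name,
             lower_bound = r$lower_bound, upper_bound = r$upper_bound,
             gene_rule = if (is.null(r$gene_rule)) "" else r$gene_rule,
             subsystem = if (is.null(r$subsystem)) "" else r$subsystem)
  })
  metabolic_model(mets, rxns,
                  objective_reaction = doc$objective,
                  id = if (is.null(doc$id)) "model" else doc$id)
}

write_model_json <- function(model, path) {
  doc <- list(
    id = model$id,
    metabolites = lapply(model$metabolites, function(m)
      Filter(Negate(is.null),
             list(id = m$id, name = m$name, compartment = m$compartment,
                  formula = m$formula, charge = m$charge))),
    reactions = lapply(model$reactions, function(r)
      list(id = r$id, name = r$name,
           stoichiometry = as.list(r$stoichiometry),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           gene_rule = r$gene_rule, subsystem = r$subsystem)),
    genes = as.list(model$genes),
    objective = model$objective_reaction
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

## ---- tabular dialect ------------------------------------------------------

#' Parse a reaction formula string
#'
#' Understands strings like `"1 glc__D_c + 2 adp_c --> 2 pyr_c + 2 atp_c"`;
#' `<=>` marks reversibility (informational only; bounds are authoritative).
#' Coefficients default to 1.
#'
#' @param s Reaction string.
#' @return List with `stoichiometry` (named numeric) and `reversible` flag.
#' @export
parse_reaction_string <- function(s) {
  arrow <- if (grepl("<=>", s, fixed = TRUE)) "<=>"
           else if (grepl("-->", s, fixed = TRUE)) "-->"
           else stop("reaction string lacks '-->' or '<=>': ", s)
  sides <- strsplit(s, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric())
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(); nm <- character()
    for (tm in terms[nzchar(terms)]) {
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 1L) {
        coef <- 1; met <- parts
      } else {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef)) stop("cannot parse term '", tm, "' in: ", s)
        met <- paste(parts[-1], collapse = " ")
      }
      nm <- c(nm, met); out <- c(out, sign * coef)
    }
    stats::setNames(out, nm)
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  stoich <- c(lhs, rhs)
  # metabolites on both sides collapse to their net coefficient
  stoich <- tapply(stoich, names(stoich), sum)
  stoich <- stats::setNames(as.numeric(stoich), names(stoich))
  stoich <- stoich[stoich != 0]
  list(stoichiometry = stoich, reversible = arrow == "<=>")
}

format_reaction_string <- function(r) {
  s <- r$stoichiometry
  fmt <- function(v, ids) {
    if (!length(ids)) return("")
    paste(ifelse(v == 1, ids, paste(format(v, trim = TRUE), ids)),
          collapse = " + ")
  }
  lhs <- fmt(abs(s[s < 0]), names(s)[s < 0])
  rhs <- fmt(s[s > 0], names(s)[s > 0])
  arrow <- if (r$lower_bound < 0) "<=>" else "-->"
  trimws(paste(lhs, arrow, rhs))
}

map_imm_space <- function(ids) sub("_i$", "_c", ids)

read_model_tabular <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  names(tab) <- tolower(gsub("[[:space:]]+", "_", names(tab)))
  required <- c("id", "formula", "lower_bound", "upper_bound")
  aliases <- c(reaction_id = "id", reaction = "id", rxn = "id",
               reaction_formula = "formula", equation = "formula",
               lb = "lower_bound", ub = "upper_bound",
               gpr = "gene_rule", gene_association = "gene_rule")
  for (a in names(aliases)) {
    if (a %in% names(tab) && !aliases[[a]] %in% names(tab)) {
      names(tab)[names(tab) == a] <- aliases[[a]]
    }
  }
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("tabular model ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  rxns <- vector("list", nrow(tab))
  met_ids <- character()
  for (k in seq_len(nrow(tab))) {
    parsed <- tryCatch(parse_reaction_string(tab$formula[k]),
                       error = function(e) stop("record ", k, " of ", path,
                                                ": ", conditionMessage(e)))
    stoich <- parsed$stoichiometry
    names(stoich) <- map_imm_space(names(stoich))
    rxns[[k]] <- reaction(
      id = tab$id[k],
      stoichiometry = stoich,
      name = if ("name" %in% names(tab)) tab$name[k] else tab$id[k],
      lower_bound = tab$lower_bound[k], upper_bound = tab$upper_bound[k],
      gene_rule = if ("gene_rule" %in% names(tab)) tab$gene_rule[k] else "",
      subsystem = if ("subsystem" %in% names(tab)) tab$subsystem[k] else "")
    met_ids <- union(met_ids, names(stoich))
  }
  mets <- lapply(sort(met_ids), metabolite)
  obj <- grep("^(DM_atp|ATPM|DM_ATP)", tab$id, value = TRUE)
  metabolic_model(mets, rxns,
                  objective_reaction = if (length(obj)) obj[1] else NULL,
                  id = tools::file_path_sans_ext(basename(path)))
}

#' Write the human-readable reaction table of a model
#'
#' One TSV row per reaction with columns `id`, `name`, `formula`,
#' `lower_bound`, `upper_bound`, `gene_rule`, `subsystem`. This is also the
#' tabular dialect accepted by [load_model()].
#'
#' @param model A `"metabolic_model"`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_reaction_table <- function(model, path) {
  tab <- data.frame(
    id = reaction_ids(model),
    name = vapply(model$reactions, `[[`, "", "name"),
    formula = vapply(model$reactions, format_reaction_string, ""),
    lower_bound = lower_bounds(model),
    upper_bound = upper_bounds(model),
    gene_rule = vapply(model$reactions, `[[`, "", "gene_rule"),
    subsystem = vapply(model$reactions, `[[`, "", "subsystem"),
    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- SBML Level 3 + FBC ---------------------------------------------------

sbml_ns <- c(
  sbml = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2"
)

sanitize_sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

write_model_sbml <- function(model, path) {
  lb <- lower_bounds(model); ub <- upper_bounds(model)
  bound_values <- sort(unique(c(lb, ub)))
  bound_id <- function(v) paste0("mf_bound_", match(v, bound_values))

  doc <- xml2::xml_new_root(
    "sbml", xmlns = sbml_ns[["sbml"]], "xmlns:fbc" = sbml_ns[["fbc"]],
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sanitize_sid(model$id),
                             "fbc:strict" = "true")

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in compartments()) {
    xml2::xml_add_child(comps, "compartment", id = cid, constant = "true")
  }

  sp <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in model$metabolites) {
    node <- xml2::xml_add_child(
      sp, "species", id = paste0("M_", sanitize_sid(m$id)), name = m$name,
      compartment = m$compartment, hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false")
    if (!is.null(m$formula)) {
      xml2::xml_set_attr(node, "fbc:chemicalFormula", m$formula)
    }
    if (!is.null(m$charge)) {
      xml2::xml_set_attr(node, "fbc:charge", as.character(m$charge))
    }
  }

  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in bound_values) {
    xml2::xml_add_child(pars, "parameter", id = bound_id(v),
                        value = format(v, digits = 17), constant = "true")
  }

  genes <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in model$genes) {
    xml2::xml_add_child(genes, "fbc:geneProduct",
                        "fbc:id" = paste0("G_", sanitize_sid(g)),
                        "fbc:label" = g)
  }

  rl <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    node <- xml2::xml_add_child(
      rl, "reaction", id = paste0("R_", sanitize_sid(r$id)), name = r$name,
      reversible = if (r$lower_bound < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = bound_id(r$lower_bound),
      "fbc:upperFluxBound" = bound_id(r$upper_bound))
    s <- r$stoichiometry
    if (any(s < 0)) {
      lr <- xml2::xml_add_child(node, "listOfReactants")
      for (met in names(s)[s < 0]) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = paste0("M_", sanitize_sid(met)),
                            stoichiometry = format(-s[[met]], digits = 17),
                            constant = "true")
      }
    }
    if (any(s > 0)) {
      lp <- xml2::xml_add_child(node, "listOfProducts")
      for (met in names(s)[s > 0]) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("M_", sanitize_sid(met)),
                            stoichiometry = format(s[[met]], digits = 17),
                            constant = "true")
      }
    }
    if (nzchar(r$gene_rule)) {
      gpa <- xml2::xml_add_child(node, "fbc:geneProductAssociation")
      add_gpr_node(gpa, parse_gpr(r$gene_rule))
    }
  }

  if (!is.null(model$objective_reaction)) {
    objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                                "fbc:activeObjective" = "obj")
    obj <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                               "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(
      lfo, "fbc:fluxObjective",
      "fbc:reaction" = paste0("R_", sanitize_sid(model$objective_reaction)),
      "fbc:coefficient" = "1")
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

# Minimal recursive-descent parser for boolean gene rules -> nested list
# with nodes list(op = "and"|"or"|"gene", children / gene).
parse_gpr <- function(rule) {
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^()[:space:]]+", rule))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_or <- function() {
    node <- parse_and()
    kids <- list(node)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); kids <- c(kids, list(parse_and()))
    }
    if (length(kids) == 1L) kids[[1]] else list(op = "or", children = kids)
  }
  parse_and <- function() {
    node <- parse_atom()
    kids <- list(node)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); kids <- c(kids, list(parse_atom()))
    }
    if (length(kids) == 1L) kids[[1]] else list(op = "and", children = kids)
  }
  parse_atom <- function() {
    t <- take()
    if (is.na(t)) stop("truncated gene rule: ", rule)
    if (t == "(") {
      node <- parse_or()
      if (!identical(take(), ")")) stop("unbalanced parentheses in: ", rule)
      node
    } else {
      list(op = "gene", gene = t)
    }
  }
  out <- parse_or()
  if (pos <= length(toks)) stop("trailing tokens in gene rule: ", rule)
  out
}

add_gpr_node <- function(parent, node) {
  if (node$op == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", sanitize_sid(node$gene)))
  } else {
    grp <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
    for (child in node$children) add_gpr_node(grp, child)
  }
}

gpr_node_to_rule <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    sub("^G_", "", xml2::xml_attr(node, "geneProduct"))
  } else if (nm %in% c("and", "or")) {
    kids <- vapply(xml2::xml_children(node), gpr_node_to_rule, "")
    paste0("(", paste(kids, collapse = paste0(" ", nm, " ")), ")")
  } else {
    stop("unexpected node in gene association: ", nm)
  }
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in ", path, ": ",
                                           conditionMessage(e)))
  ns <- c(s = sbml_ns[["sbml"]], fbc = sbml_ns[["fbc"]])
  mdl <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path)

  strip <- function(x, prefix) sub(paste0("^", prefix), "", x)
  pars <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                             xml2::xml_attr(pars, "id"))

  species <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- lapply(species, function(node) {
    id <- map_imm_space(strip(xml2::xml_attr(node, "id"), "M_"))
    comp <- xml2::xml_attr(node, "compartment")
    if (identical(comp, "i")) comp <- "c"
    ch <- xml2::xml_attr(node, "fbc:charge", ns = ns)
    metabolite(id = id,
               name = {
                 nmv <- xml2::xml_attr(node, "name")
                 if (is.na(nmv)) id else nmv
               },
               compartment = comp,
               formula = {
                 f <- xml2::xml_attr(node, "fbc:chemicalFormula", ns = ns)
                 if (is.na(f)) NULL else f
               },
               charge = if (is.na(ch)) NULL else as.integer(ch))
  })

  rxn_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rxn_nodes, function(node) {
    id <- strip(xml2::xml_attr(node, "id"), "R_")
    get_refs <- function(xpath, sign) {
      refs <- xml2::xml_find_all(node, xpath, ns)
      stats::setNames(
        sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
        map_imm_space(strip(xml2::xml_attr(refs, "species"), "M_")))
    }
    stoich <- c(get_refs("./s:listOfReactants/s:speciesReference", -1),
                get_refs("./s:listOfProducts/s:speciesReference", +1))
    lb_id <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns = ns)
    ub_id <- xml2::xml_attr(node, "fbc:upperFluxBound", ns = ns)
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation/*", ns)
    rule <- if (inherits(gpa, "xml_missing")) "" else gpr_node_to_rule(gpa)
    rule <- gsub("^\\(|\\)$", "", rule)
    reaction(id = id, stoichiometry = stoich,
             name = {
               nmv <- xml2::xml_attr(node, "name")
               if (is.na(nmv)) id else nmv
             },
             lower_bound = par_val[[lb_id]], upper_bound = par_val[[ub_id]],
             gene_rule = rule)
  })

  obj_ref <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  objective <- if (inherits(obj_ref, "xml_missing")) NULL else
    strip(xml2::xml_attr(obj_ref, "fbc:reaction", ns = ns), "R_")

  metabolic_model(mets, rxns, objective_reaction = objective,
                  id = {
                    mid <- xml2::xml_attr(mdl, "id")
                    if (is.na(mid)) "model" else mid
                  })
}

## ---- elemental bookkeeping ------------------------------------------------

#' Parse an elemental composition string
#'
#' @param formula String such as `"C21H36N7O16P3S"`.
#' @return Named numeric vector of element counts.
#' @export
formula_elements <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) {
    return(stats::setNames(numeric(), character()))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (!length(parts) || sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  n <- sub("^[A-Z][a-z]?", "", parts)
  counts <- ifelse(nzchar(n), as.numeric(n), 1)
  tapply(counts, el, sum)
}

#' Audit elemental balance of a model's reactions
#'
#' Exchange reactions and demand/sink reactions (ids prefixed `EX_`, `DM_`,
#' `SINK_`) are boundary reactions and intentionally unbalanced; all other
#' reactions should conserve every element for which the participating
#' metabolites carry formulas.
#'
#' @param model A `"metabolic_model"` whose metabolites carry `formula`s.
#' @param elements Elements to audit.
#' @param tol Absolute imbalance tolerated per element.
#' @return Data frame with one row per audited reaction and one column per
#'   element giving the net imbalance (products minus substrates); an
#'   attribute `"balanced"` reports whether all imbalances are below `tol`.
#' @export
check_elemental_balance <- function(model,
                                    elements = c("C", "H", "N", "O", "P", "S"),
                                    tol = 1e-9) {
  met_formula <- stats::setNames(
    lapply(model$metabolites, function(m) formula_elements(m$formula)),
    metabolite_ids(model))
  boundary <- grepl("^(EX_|DM_|SINK_)", reaction_ids(model))
  rxns <- model$reactions[!boundary]
  out <- matrix(0, nrow = length(rxns), ncol = length(elements),
                dimnames = list(vapply(rxns, `[[`, "", "id"), elements))
  for (k in seq_along(rxns)) {
    s <- rxns[[k]]$stoichiometry
    for (met in names(s)) {
      f <- met_formula[[met]]
      common <- intersect(names(f), elements)
      out[k, common] <- out[k, common] + s[[met]] * f[common]
    }
  }
  res <- as.data.frame(out)
  attr(res, "balanced") <- all(abs(out) < tol)
  res
}
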