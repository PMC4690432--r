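# SBML subset reader/writer.
#
# Supported on read: SBML Level 2 (any version) and Level 3 Version 1;
# compartments, species (amounts; declared concentrations are converted via
# compartment size at load), global parameters, reactions with kinetic laws,
# rate rules and assignment rules. Events, delays, algebraic rules, function
# definitions, initial assignments, constraints and local reaction parameters
# raise UnsupportedFeature. Written files are always Level 3 Version 1.
#
# Species values are handled as AMOUNTS throughout, and identifiers in
# kinetic laws are interpreted as amounts (exact SBML semantics when all
# compartment sizes are 1, which holds for every shipped fixture).

SBML_L3_NS <- "http://www.sbml.org/sbml/level3/version1/core"

#' Construct a base model
#'
#' The in-memory form of the supported SBML subset. Usually produced by
#' [load_sbml()] or [example_model()]; exposed so toy models can be built in
#' code.
#'
#' @param model_id model identifier.
#' @param compartments data.frame with columns `id`, `size`, `constant`.
#' @param species data.frame with columns `id`, `compartment`,
#'   `initial_amount`, `boundary`.
#' @param quantities data.frame with columns `id`, `value`, `constant`
#'   (the SBML global parameters).
#' @param reactions list; each element a list with `id`, `reactants` and
#'   `products` (data.frames with `species`, `stoichiometry`), `modifiers`
#'   (character) and `law` (an expression AST or string).
#' @param rate_rules,assignment_rules lists of `list(target =, math =)`.
#' @return An object of class `mg_model`.
#' @export
base_model <- function(model_id = "model",
                       compartments = data.frame(id = character(), size = numeric(),
                                                 constant = logical()),
                       species = data.frame(id = character(), compartment = character(),
                                            initial_amount = numeric(), boundary = logical()),
                       quantities = data.frame(id = character(), value = numeric(),
                                               constant = logical()),
                       reactions = list(),
                       rate_rules = list(),
                       assignment_rules = list()) {
  reactions <- lapply(reactions, function(r) {
    r$law <- as_expr_ast(r$law)
    if (is.null(r$modifiers)) r$modifiers <- character()
    r$reactants <- as_stoich_df(r$reactants)
    r$products <- as_stoich_df(r$products)
    r
  })
  fix_rule <- function(rl) {
    rl$math <- as_expr_ast(rl$math)
    rl
  }
  m <- structure(list(model_id = model_id,
                      compartments = compartments,
                      species = species,
                      quantities = quantities,
                      reactions = reactions,
                      rate_rules = lapply(rate_rules, fix_rule),
                      assignment_rules = lapply(assignment_rules, fix_rule)),
                 class = "mg_model")
  validate_model(m)
  m
}

as_stoich_df <- function(x) {
  if (is.null(x))
    return(data.frame(species = character(), stoichiometry = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(species = as.character(x$species),
             stoichiometry = as.numeric(x$stoichiometry),
             stringsAsFactors = FALSE)
}

validate_model <- function(m) {
  ids <- c(m$compartments$id, m$species$id, m$quantities$id,
           vapply(m$reactions, function(r) r$id, ""))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    mg_stop("mg_sbml_parse_error",
            sprintf("duplicate identifier(s): %s", paste(unique(dup), collapse = ", ")))
  bad_comp <- setdiff(m$species$compartment, m$compartments$id)
  if (length(bad_comp) > 0L)
    mg_stop("mg_sbml_parse_error",
            sprintf("species reference unknown compartment(s): %s",
                    paste(bad_comp, collapse = ", ")))
  known <- c(m$compartments$id, m$species$id, m$quantities$id)
  for (r in m$reactions) {
    for (sp in c(r$reactants$species, r$products$species, r$modifiers))
      if (!sp %in% m$species$id)
        mg_stop("mg_sbml_parse_error",
                sprintf("reaction '%s' references unknown species '%s'", r$id, sp))
    if (any(r$reactants$stoichiometry <= 0) || any(r$products$stoichiometry <= 0))
      mg_stop("mg_sbml_parse_error",
              sprintf("reaction '%s' has a non-positive stoichiometry", r$id))
    refs <- expr_refs(r$law)
    unknown <- setdiff(refs$key, known)
    if (length(unknown) > 0L)
      mg_stop("mg_sbml_parse_error",
              sprintf("kinetic law of '%s' references undeclared identifier(s): %s",
                      r$id, paste(unknown, collapse = ", ")))
  }
  for (rl in c(m$rate_rules, m$assignment_rules)) {
    if (!rl$target %in% known)
      mg_stop("mg_sbml_parse_error",
              sprintf("rule targets unknown identifier '%s'", rl$target))
    unknown <- setdiff(expr_refs(rl$math)$key, known)
    if (length(unknown) > 0L)
      mg_stop("mg_sbml_parse_error",
              sprintf("rule for '%s' references undeclared identifier(s): %s",
                      rl$target, paste(unknown, collapse = ", ")))
  }
  invisible(m)
}

# ---- reading -----------------------------------------------------------------

#' Load an SBML model (Level 2 or Level 3 Version 1)
#'
#' Unsupported constructs (events, algebraic rules, delays, function
#' definitions, initial assignments, local reaction parameters) raise an
#' explicit error rather than being dropped.
#'
#' @param path path to an SBML file.
#' @return An object of class `mg_model`.
#' @export
load_sbml <- function(path) {
  if (!file.exists(path))
    mg_stop("mg_file_not_found", sprintf("no such file: %s", path), path = path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    mg_stop("mg_sbml_parse_error", sprintf("not parseable XML: %s", conditionMessage(e))))
  xml2::xml_ns_strip(doc)
  root <- doc
  if (xml2::xml_name(root) != "sbml")
    mg_stop("mg_sbml_parse_error", "root element is not <sbml>")
  level <- as.integer(xml2::xml_attr(root, "level"))
  version <- as.integer(xml2::xml_attr(root, "version"))
  if (is.na(level) || !(level == 2L || (level == 3L && version == 1L)))
    mg_stop("mg_unsupported_feature",
            sprintf("SBML Level %s Version %s is not supported (need L2 or L3V1)",
                    level, version),
            feature = "sbml level")
  model <- xml2::xml_find_first(root, "./model")
  if (inherits(model, "xml_missing"))
    mg_stop("mg_sbml_parse_error", "no <model> element")

  reject <- function(xpath, feature) {
    if (length(xml2::xml_find_all(model, xpath)) > 0L)
      mg_stop("mg_unsupported_feature",
              sprintf("model uses unsupported construct: %s", feature),
              feature = feature)
  }
  reject(".//event", "events")
  reject(".//algebraicRule", "algebraic rules")
  reject(".//functionDefinition", "function definitions")
  reject(".//initialAssignment", "initial assignments")
  reject(".//constraint", "constraints")
  reject(".//kineticLaw//parameter | .//kineticLaw//localParameter",
         "local reaction parameters")
  reject(".//csymbol[contains(@definitionURL, 'delay')]", "delay")

  num_attr <- function(node, attr, default = NA_real_) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v)) default else as.numeric(v)
  }
  bool_attr <- function(node, attr, default = FALSE) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v)) default else identical(v, "true")
  }

  comps <- xml2::xml_find_all(model, "./listOfCompartments/compartment")
  compartments <- data.frame(
    id = xml2::xml_attr(comps, "id"),
    size = vapply(comps, function(x) {
      s <- num_attr(x, "size")
      if (is.na(s)) s <- num_attr(x, "volume") # L1/L2 synonym
      if (is.na(s)) 1 else s
    }, 0),
    constant = vapply(comps, bool_attr, TRUE, attr = "constant", default = TRUE),
    stringsAsFactors = FALSE)

  sps <- xml2::xml_find_all(model, "./listOfSpecies/species")
  species <- data.frame(
    id = xml2::xml_attr(sps, "id"),
    compartment = xml2::xml_attr(sps, "compartment"),
    initial_amount = NA_real_,
    boundary = vapply(sps, bool_attr, TRUE, attr = "boundaryCondition",
                      default = FALSE),
    stringsAsFactors = FALSE)
  if (nrow(species) > 0L) {
    sizes <- stats::setNames(compartments$size, compartments$id)
    species$initial_amount <- vapply(seq_along(sps), function(i) {
      amt <- num_attr(sps[[i]], "initialAmount")
      if (!is.na(amt)) return(amt)
      conc <- num_attr(sps[[i]], "initialConcentration")
      if (!is.na(conc)) {
        sz <- sizes[[species$compartment[i]]]
        if (is.null(sz) || is.na(sz)) sz <- 1
        return(conc * sz)
      }
      0
    }, 0)
  }

  pars <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  quantities <- data.frame(
    id = xml2::xml_attr(pars, "id"),
    value = vapply(pars, num_attr, 0, attr = "value", default = 0),
    constant = vapply(pars, bool_attr, TRUE, attr = "constant", default = TRUE),
    stringsAsFactors = FALSE)

  read_math <- function(node, what) {
    m <- xml2::xml_find_first(node, "./math")
    if (inherits(m, "xml_missing"))
      mg_stop("mg_sbml_parse_error", sprintf("%s has no <math>", what))
    mathml_to_ast(m)
  }

  rules <- xml2::xml_find_all(model, "./listOfRules/*")
  rate_rules <- list()
  assignment_rules <- list()
  for (rl in rules) {
    target <- xml2::xml_attr(rl, "variable")
    entry <- list(target = target, math = read_math(rl, "rule"))
    if (xml2::xml_name(rl) == "rateRule") {
      rate_rules[[length(rate_rules) + 1L]] <- entry
    } else if (xml2::xml_name(rl) == "assignmentRule") {
      assignment_rules[[length(assignment_rules) + 1L]] <- entry
    } else {
      mg_stop("mg_unsupported_feature",
              sprintf("unsupported rule type <%s>", xml2::xml_name(rl)),
              feature = xml2::xml_name(rl))
    }
  }

  rxns <- xml2::xml_find_all(model, "./listOfReactions/reaction")
  reactions <- lapply(rxns, function(rx) {
    refs <- function(xpath) {
      srefs <- xml2::xml_find_all(rx, xpath)
      data.frame(
        species = xml2::xml_attr(srefs, "species"),
        stoichiometry = vapply(srefs, num_attr, 0, attr = "stoichiometry",
                               default = 1),
        stringsAsFactors = FALSE)
    }
    kl <- xml2::xml_find_first(rx, "./kineticLaw")
    if (inherits(kl, "xml_missing"))
      mg_stop("mg_sbml_parse_error",
              sprintf("reaction '%s' has no kinetic law", xml2::xml_attr(rx, "id")))
    list(id = xml2::xml_attr(rx, "id"),
         reactants = refs("./listOfReactants/speciesReference"),
         products = refs("./listOfProducts/speciesReference"),
         modifiers = xml2::xml_attr(
           xml2::xml_find_all(rx, "./listOfModifiers/modifierSpeciesReference"),
           "species"),
         law = read_math(kl, "kinetic law"))
  })

  mid <- xml2::xml_attr(model, "id")
  if (is.na(mid) || !nzchar(mid)) mid <- "model"
  m <- structure(list(model_id = mid,
                      compartments = compartments,
                      species = species,
                      quantities = quantities,
                      reactions = reactions,
                      rate_rules = rate_rules,
                      assignment_rules = assignment_rules),
                 class = "mg_model")
  validate_model(m)
  m
}

# ---- writing -----------------------------------------------------------------

#' Write a model as SBML Level 3 Version 1
#'
#' @param model an `mg_model`.
#' @param path output file path, or `NULL` to return the serialized document
#'   as a string.
#' @return `path` invisibly (or the XML string when `path` is `NULL`).
#' @export
write_sbml <- function(model, path = NULL) {
  validate_model(model)
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_L3_NS,
                            level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = model$model_id)
  fmt <- function(v) sprintf("%.17g", v)
  tf <- function(b) if (isTRUE(b)) "true" else "false"

  if (nrow(model$compartments) > 0L) {
    loc <- xml2::xml_add_child(mdl, "listOfCompartments")
    for (i in seq_len(nrow(model$compartments)))
      xml2::xml_add_child(loc, "compartment",
                          id = model$compartments$id[i],
                          size = fmt(model$compartments$size[i]),
                          constant = tf(model$compartments$constant[i]))
  }
  if (nrow(model$species) > 0L) {
    los <- xml2::xml_add_child(mdl, "listOfSpecies")
    for (i in seq_len(nrow(model$species)))
      xml2::xml_add_child(los, "species",
                          id = model$species$id[i],
                          compartment = model$species$compartment[i],
                          initialAmount = fmt(model$species$initial_amount[i]),
                          hasOnlySubstanceUnits = "true",
                          boundaryCondition = tf(model$species$boundary[i]),
                          constant = "false")
  }
  if (nrow(model$quantities) > 0L) {
    lop <- xml2::xml_add_child(mdl, "listOfParameters")
    for (i in seq_len(nrow(model$quantities)))
      xml2::xml_add_child(lop, "parameter",
                          id = model$quantities$id[i],
                          value = fmt(model$quantities$value[i]),
                          constant = tf(model$quantities$constant[i]))
  }
  if (length(model$rate_rules) + length(model$assignment_rules) > 0L) {
    lor <- xml2::xml_add_child(mdl, "listOfRules")
    for (rl in model$assignment_rules) {
      nd <- xml2::xml_add_child(lor, "assignmentRule", variable = rl$target)
      math_element(nd, rl$math)
    }
    for (rl in model$rate_rules) {
      nd <- xml2::xml_add_child(lor, "rateRule", variable = rl$target)
      math_element(nd, rl$math)
    }
  }
  if (length(model$reactions) > 0L) {
    lorx <- xml2::xml_add_child(mdl, "listOfReactions")
    for (r in model$reactions) {
      rx <- xml2::xml_add_child(lorx, "reaction", id = r$id,
                                reversible = "false", fast = "false")
      add_refs <- function(df, listname, refname) {
        if (nrow(df) == 0L) return(invisible(NULL))
        lst <- xml2::xml_add_child(rx, listname)
        for (i in seq_len(nrow(df)))
          xml2::xml_add_child(lst, refname,
                              species = df$species[i],
                              stoichiometry = fmt(df$stoichiometry[i]),
                              constant = "true")
      }
      add_refs(r$reactants, "listOfReactants", "speciesReference")
      add_refs(r$products, "listOfProducts", "speciesReference")
      if (length(r$modifiers) > 0L) {
        lom <- xml2::xml_add_child(rx, "listOfModifiers")
        for (sp in r$modifiers)
          xml2::xml_add_child(lom, "modifierSpeciesReference", species = sp)
      }
      kl <- xml2::xml_add_child(rx, "kineticLaw")
      math_element(kl, r$law)
    }
  }
  if (is.null(path)) return(as.character(doc))
  xml2::write_xml(doc, path)
  invisible(path)
}

# ---- base set ----------------------------------------------------------------

#' Extract the base set of assignable values
#'
#' The base set holds one entry per global quantity (unless computed by an
#' assignment rule), per non-boundary species initial amount, and per
#' compartment size — the quantities a configuration node may override.
#'
#' @param model an `mg_model`.
#' @return A list with `values` (named numeric) and `category` (named
#'   character: `GLOBAL_QUANTITY`, `SPECIES_INITIAL` or `COMPARTMENT_SIZE`),
#'   of class `mg_base_set`.
#' @export
base_set <- function(model) {
  assigned <- vapply(model$assignment_rules, function(r) r$target, "")
  qs <- model$quantities[!model$quantities$id %in% assigned, , drop = FALSE]
  sp <- model$species[!model$species$boundary & !model$species$id %in% assigned, ,
                      drop = FALSE]
  values <- c(stats::setNames(qs$value, qs$id),
              stats::setNames(sp$initial_amount, sp$id),
              stats::setNames(model$compartments$size, model$compartments$id))
  category <- c(stats::setNames(rep("GLOBAL_QUANTITY", nrow(qs)), qs$id),
                stats::setNames(rep("SPECIES_INITIAL", nrow(sp)), sp$id),
                stats::setNames(rep("COMPARTMENT_SIZE", nrow(model$compartments)),
                                model$compartments$id))
  structure(list(values = values, category = category), class = "mg_base_set")
}

#' Apply resolved values to a model ("flattening")
#'
#' Returns a copy of the model whose initial values are replaced by `values`;
#' structure (reactions, math) is untouched.
#'
#' @param model an `mg_model`.
#' @param values named numeric vector or list; every name must be a base-set
#'   key of `model`.
#' @return The flattened `mg_model`.
#' @export
apply_values <- function(model, values) {
  values <- unlist(values)
  if (length(values) == 0L) return(model)
  bs <- base_set(model)
  unknown <- setdiff(names(values), names(bs$values))
  if (length(unknown) > 0L)
    mg_stop("mg_unknown_key",
            sprintf("not assignable in this model: %s", paste(unknown, collapse = ", ")),
            keys = unknown)
  for (key in names(values)) {
    v <- as.numeric(values[[key]])
    switch(bs$category[[key]],
           GLOBAL_QUANTITY = {
             model$quantities$value[model$quantities$id == key] <- v
           },
           SPECIES_INITIAL = {
             model$species$initial_amount[model$species$id == key] <- v
           },
           COMPARTMENT_SIZE = {
             model$compartments$size[model$compartments$id == key] <- v
           })
  }
  model
}

#' Validate a model against the structural rules of the supported subset
#'
#' Checks id uniqueness across all categories, compartment references,
#' stoichiometry positivity, and that all math references declared ids.
#'
#' @param model an `mg_model`.
#' @return The model, invisibly; raises an SBML parse error otherwise.
#' @export
validate_sbml_model <- function(model) validate_model(model)

#' @export
print.mg_model <- function(x, ...) {
  cat(sprintf("<mg_model> %s: %d compartment(s), %d species, %d quantit%s, %d reaction(s)\n",
              x$model_id, nrow(x$compartments), nrow(x$species),
              nrow(x$quantities), if (nrow(x$quantities) == 1L) "y" else "ies",
              length(x$reactions)))
  invisible(x)
}

# Field-wise model equality (used by round-trip tests and fixpoint checks).
models_equal <- function(a, b, tol = 1e-12) {
  num_eq <- function(x, y) length(x) == length(y) && all(abs(x - y) <= tol)
  if (!identical(a$model_id, b$model_id)) return(FALSE)
  if (!identical(a$compartments$id, b$compartments$id) ||
      !num_eq(a$compartments$size, b$compartments$size) ||
      !identical(a$compartments$constant, b$compartments$constant)) return(FALSE)
  if (!identical(a$species$id, b$species$id) ||
      !identical(a$species$compartment, b$species$compartment) ||
      !num_eq(a$species$initial_amount, b$species$initial_amount) ||
      !identical(a$species$boundary, b$species$boundary)) return(FALSE)
  if (!identical(a$quantities$id, b$quantities$id) ||
      !num_eq(a$quantities$value, b$quantities$value) ||
      !identical(a$quantities$constant, b$quantities$constant)) return(FALSE)
  if (length(a$reactions) != length(b$reactions)) return(FALSE)
  for (i in seq_along(a$reactions)) {
    ra <- a$reactions[[i]]; rb <- b$reactions[[i]]
    if (!identical(ra$id, rb$id)) return(FALSE)
    if (!identical(ra$reactants$species, rb$reactants$species) ||
        !num_eq(ra$reactants$stoichiometry, rb$reactants$stoichiometry)) return(FALSE)
    if (!identical(ra$products$species, rb$products$species) ||
        !num_eq(ra$products$stoichiometry, rb$products$stoichiometry)) return(FALSE)
    if (!identical(ra$modifiers, rb$modifiers)) return(FALSE)
    if (!identical(format_expr(ra$law), format_expr(rb$law))) return(FALSE)
  }
  rules_eq <- function(x, y) {
    if (length(x) != length(y)) return(FALSE)
    for (i in seq_along(x))
      if (!identical(x[[i]]$target, y[[i]]$target) ||
          !identical(format_expr(x[[i]]$math), format_expr(y[[i]]$math)))
        return(FALSE)
    TRUE
  }
  rules_eq(a$rate_rules, b$rate_rules) &&
    rules_eq(a$assignment_rules, b$assignment_rules)
}
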