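#' Read a metabolic model from SBML (L3/FBC) or BiGG-style JSON
#'
#' Infinite or missing bounds in the file are mapped to `+/- big_bound`
#' (1000 by default, the BiGG convention) so that the induced linear program
#' is finite.
#'
#' @param path Path to the model file.
#' @param format `"bigg_json"`, `"sbml"`, or `"auto"` (by file extension).
#' @param big_bound Magnitude substituted for infinite bounds.
#' @return A validated [stoich_model()].
#' @export
read_model <- function(path, format = c("auto", "bigg_json", "sbml"),
                       big_bound = 1000) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
              else "bigg_json"
  }
  model <- switch(format,
    bigg_json = read_model_bigg_json(path, big_bound),
    sbml = read_model_sbml(path, big_bound)
  )
  stop_on_invalid(model)
  model
}

clamp_bound <- function(x, big_bound) {
  x <- as.numeric(x)
  x[!is.finite(x) & x > 0] <- big_bound
  x[!is.finite(x) & x < 0] <- -big_bound
  x[is.na(x)] <- 0
  pmin(pmax(x, -big_bound), big_bound)
}

read_model_bigg_json <- function(path, big_bound) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(sprintf("cannot parse '%s' as JSON: %s",
                                      path, conditionMessage(e)))
  )
  for (fld in c("metabolites", "reactions")) {
    if (is.null(doc[[fld]])) {
      abort(sprintf("malformed model file '%s': missing element '%s'", path, fld))
    }
  }
  mets <- bind_rows(lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) abort(sprintf("malformed metabolite entry in '%s' (no id)", path))
    tibble(id = m$id,
           name = m$name %||% m$id,
           compartment = m$compartment %||% guess_compartment(m$id),
           formula = m$formula %||% NA_character_,
           charge = as.integer(m$charge %||% NA_integer_))
  }))
  obj <- NULL
  rxns <- bind_rows(lapply(doc$reactions, function(r) {
    if (is.null(r$id)) abort(sprintf("malformed reaction entry in '%s' (no id)", path))
    st <- unlist(r$metabolites)
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0) {
      obj <<- r$id
    }
    tibble(id = r$id,
           name = r$name %||% r$id,
           stoichiometry = list(st),
           lower_bound = clamp_bound(r$lower_bound %||% -big_bound, big_bound),
           upper_bound = clamp_bound(r$upper_bound %||% big_bound, big_bound),
           subsystem = r$subsystem %||% NA_character_)
  }))
  cps <- unlist(doc$compartments)
  if (is.null(cps)) {
    ids <- unique(mets$compartment)
    cps <- setNames(ids, ids)
  } else {
    cps <- setNames(as.character(cps), names(cps))
  }
  if (is.null(obj)) obj <- rxns$id[1]
  stoich_model(metabolites = mets, reactions = rxns, compartments = cps,
               objective = obj, id = doc$id %||% basename(path))
}

guess_compartment <- function(id) {
  m <- regmatches(id, regexpr("_[a-z]$", id))
  if (length(m) == 1L) sub("^_", "", m) else "c"
}

#' Write a model as BiGG-style JSON
#'
#' @param model A [stoich_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  doc <- list(
    id = model$id,
    compartments = as.list(model$compartments),
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) out$formula <- m$formula
      if (!is.na(m$charge)) out$charge <- m$charge
      out
    }),
    reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
      r <- model$reactions[i, ]
      st <- r$stoichiometry[[1]]
      out <- list(id = r$id, name = r$name,
                  metabolites = as.list(st),
                  lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                  objective_coefficient = as.numeric(r$id == model$objective))
      if (!is.na(r$subsystem)) out$subsystem <- r$subsystem
      out
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# --- SBML Level 3 with the fbc package -------------------------------------

read_model_sbml <- function(path, big_bound) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(sprintf(
                    "cannot parse '%s' as XML: %s", path, conditionMessage(e))))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  mod <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mod, "xml_missing")) {
    abort(sprintf("malformed SBML file '%s': no <model> element", path))
  }
  attr_or <- function(node, a, default = NA_character_) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) default else v
  }

  cp_nodes <- xml2::xml_find_all(mod, ".//s:listOfCompartments/s:compartment", ns)
  cps <- setNames(
    vapply(cp_nodes, function(n) attr_or(n, "name", xml2::xml_attr(n, "id")), ""),
    vapply(cp_nodes, function(n) xml2::xml_attr(n, "id"), "")
  )

  par_nodes <- xml2::xml_find_all(mod, ".//s:listOfParameters/s:parameter", ns)
  pars <- setNames(
    vapply(par_nodes, function(n) as.numeric(attr_or(n, "value", "NA")), 0),
    vapply(par_nodes, function(n) xml2::xml_attr(n, "id"), "")
  )

  sp_nodes <- xml2::xml_find_all(mod, ".//s:listOfSpecies/s:species", ns)
  mets <- bind_rows(lapply(sp_nodes, function(n) {
    tibble(id = xml2::xml_attr(n, "id"),
           name = attr_or(n, "name", xml2::xml_attr(n, "id")),
           compartment = xml2::xml_attr(n, "compartment"),
           formula = attr_or(n, "chemicalFormula") %||%
                     xml2::xml_attr(n, "fbc:chemicalFormula"),
           charge = suppressWarnings(as.integer(xml2::xml_attr(n, "charge"))))
  }))

  rx_nodes <- xml2::xml_find_all(mod, ".//s:listOfReactions/s:reaction", ns)
  bound_of <- function(node, which, fallback) {
    ref <- xml2::xml_attr(node, which)
    if (!is.na(ref) && ref %in% names(pars)) pars[[ref]] else fallback
  }
  rxns <- bind_rows(lapply(rx_nodes, function(n) {
    id <- xml2::xml_attr(n, "id")
    reac <- xml2::xml_find_all(n, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(n, "./s:listOfProducts/s:speciesReference", ns)
    sto <- function(nodes, sign) {
      setNames(
        sign * vapply(nodes, function(x) as.numeric(attr_or(x, "stoichiometry", "1")), 0),
        vapply(nodes, function(x) xml2::xml_attr(x, "species"), "")
      )
    }
    st <- c(sto(reac, -1), sto(prod, 1))
    st <- tapply(st, names(st), sum)  # merge species on both sides
    st <- setNames(as.numeric(st), names(st))
    st <- st[st != 0]
    reversible <- identical(xml2::xml_attr(n, "reversible"), "true")
    lb_default <- if (reversible) -big_bound else 0
    tibble(id = id, name = attr_or(n, "name", id),
           stoichiometry = list(st),
           lower_bound = clamp_bound(bound_of(n, "lowerFluxBound", lb_default), big_bound),
           upper_bound = clamp_bound(bound_of(n, "upperFluxBound", big_bound), big_bound),
           subsystem = NA_character_)
  }))

  obj_node <- xml2::xml_find_first(
    mod, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  obj <- if (!inherits(obj_node, "xml_missing")) {
    xml2::xml_attr(obj_node, "reaction")
  } else {
    rxns$id[1]
  }
  stoich_model(metabolites = mets, reactions = rxns, compartments = cps,
               objective = obj, id = attr_or(mod, "id", basename(path)))
}
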