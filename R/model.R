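#' Construct a stoichiometric metabolic model
#'
#' A `stoich_model` bundles compartments, metabolites, reactions and the
#' biomass objective of a constraint-based metabolic model. It induces the
#' stoichiometric matrix S (one row per metabolite, one column per reaction),
#' the flux bound vectors lb/ub and the objective vector c used by
#' [solve_fba()].
#'
#' Exchange reactions follow the BiGG/SBML-FBC sign convention: they touch
#' exactly one metabolite, and negative flux means uptake, positive flux
#' secretion.
#'
#' @param metabolites A data frame with columns `id`, `compartment` and
#'   optionally `name`, `formula`, `charge`.
#' @param reactions A data frame with columns `id`, `stoichiometry` (a list
#'   column of named numeric vectors, names are metabolite ids, values signed
#'   coefficients), `lower_bound`, `upper_bound`, and optionally `name`,
#'   `subsystem`.
#' @param compartments Named character vector mapping compartment ids to
#'   display names, e.g. `c(c = "cytosol", m = "mitochondria")`. Defaults to
#'   the compartments referenced by `metabolites`.
#' @param objective Reaction id of the (biomass) objective reaction.
#' @param id Optional model identifier string.
#'
#' @return An object of class `stoich_model`.
#' @seealso [validate_model()], [stoichiometric_matrix()], [read_model()]
#' @export
#' @examples
#' m <- stoich_model(
#'   metabolites = tibble::tibble(id = c("A_c", "B_c"), compartment = "c"),
#'   reactions = tibble::tibble(
#'     id = c("EX_A", "R1", "EX_B"),
#'     stoichiometry = list(c(A_c = -1), c(A_c = -1, B_c = 1), c(B_c = -1)),
#'     lower_bound = c(-10, 0, 0),
#'     upper_bound = c(0, 1000, 1000)
#'   ),
#'   objective = "EX_B"
#' )
#' m
stoich_model <- function(metabolites, reactions, compartments = NULL,
                         objective, id = "model") {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  if (!"charge" %in% names(metabolites)) metabolites$charge <- NA_integer_
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- NA_character_
  metabolites <- metabolites[, c("id", "name", "compartment", "formula", "charge")]
  reactions$is_exchange <- vapply(reactions$stoichiometry, length, 1L) == 1L
  reactions <- reactions[, c("id", "name", "stoichiometry", "lower_bound",
                             "upper_bound", "subsystem", "is_exchange")]
  if (is.null(compartments)) {
    cps <- unique(metabolites$compartment)
    compartments <- setNames(cps, cps)
  }
  if (is.null(names(compartments))) {
    compartments <- setNames(compartments, compartments)
  }
  structure(
    list(id = id, compartments = compartments, metabolites = metabolites,
         reactions = reactions, objective = objective),
    class = "stoich_model"
  )
}

#' @export
print.stoich_model <- function(x, ...) {
  cat(sprintf("<stoich_model> %s\n", x$id))
  cat(sprintf("  compartments: %s\n", paste(names(x$compartments), collapse = ", ")))
  cat(sprintf("  metabolites:  %d\n", nrow(x$metabolites)))
  cat(sprintf("  reactions:    %d (%d exchange)\n", nrow(x$reactions),
              sum(x$reactions$is_exchange)))
  cat(sprintf("  objective:    %s\n", x$objective))
  invisible(x)
}

rxn_row <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) abort(sprintf("unknown reaction id '%s'", id))
  i
}

met_row <- function(model, id) {
  i <- match(id, model$metabolites$id)
  if (is.na(i)) abort(sprintf("unknown metabolite id '%s'", id))
  i
}

#' Set flux bounds on one reaction
#'
#' @param model A [stoich_model()].
#' @param id Reaction id.
#' @param lower_bound,upper_bound New bounds; `NULL` leaves a bound unchanged.
#' @return The modified model (the input is not mutated).
#' @export
set_bounds <- function(model, id, lower_bound = NULL, upper_bound = NULL) {
  i <- rxn_row(model, id)
  if (!is.null(lower_bound)) model$reactions$lower_bound[i] <- lower_bound
  if (!is.null(upper_bound)) model$reactions$upper_bound[i] <- upper_bound
  model
}

#' Reaction bounds as a tibble
#'
#' @param model A [stoich_model()].
#' @return A tibble with columns `id`, `lower_bound`, `upper_bound`.
#' @export
reaction_bounds <- function(model) {
  model$reactions[, c("id", "lower_bound", "upper_bound")]
}

#' Stoichiometric matrix of a model
#'
#' Builds the sparse stoichiometric matrix S with one row per metabolite and
#' one column per reaction; entry (m, r) is the signed coefficient of
#' metabolite m in reaction r, zero elsewhere. Row order follows
#' `model$metabolites`, column order `model$reactions`; both orders are stable
#' and carried as dimnames.
#'
#' @param model A [stoich_model()].
#' @return A `Matrix::dgCMatrix` of dimension (metabolites x reactions).
#' @export
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxns)) {
    st <- model$reactions$stoichiometry[[j]]
    i <- match(names(st), mets)
    if (anyNA(i)) {
      abort(sprintf("reaction '%s' references unknown metabolite(s): %s",
                    rxns[j], paste(names(st)[is.na(i)], collapse = ", ")))
    }
    ii <- c(ii, i); jj <- c(jj, rep.int(j, length(st))); xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mets), length(rxns)),
                       dimnames = list(mets, rxns))
}

#' Validate a stoichiometric model
#'
#' Checks every structural invariant of the model and reports violations as
#' diagnostics rather than raising errors: duplicate ids, unknown
#' compartments, dangling metabolite references, empty stoichiometries,
#' inverted bounds, exchange reactions touching more than one metabolite, a
#' missing objective reaction, and orphan metabolites (warning level).
#'
#' @param model A [stoich_model()].
#' @return A tibble with columns `level` ("error" or "warning"), `code`, `id`
#'   and `message`; zero rows iff all invariants hold.
#' @export
validate_model <- function(model) {
  out <- list()
  note <- function(level, code, id, msg) {
    out[[length(out) + 1L]] <<- tibble(level = level, code = code, id = id,
                                       message = msg)
  }
  mets <- model$metabolites
  rxns <- model$reactions

  dup <- mets$id[duplicated(mets$id)]
  for (d in unique(dup)) note("error", "duplicate_metabolite", d,
                              sprintf("metabolite id '%s' is not unique", d))
  dup <- rxns$id[duplicated(rxns$id)]
  for (d in unique(dup)) note("error", "duplicate_reaction", d,
                              sprintf("reaction id '%s' is not unique", d))
  bad_cp <- !mets$compartment %in% names(model$compartments)
  for (i in which(bad_cp)) {
    note("error", "unknown_compartment", mets$id[i],
         sprintf("metabolite '%s' references undeclared compartment '%s'",
                 mets$id[i], mets$compartment[i]))
  }
  used <- character(0)
  for (j in seq_len(nrow(rxns))) {
    st <- rxns$stoichiometry[[j]]
    if (length(st) == 0L) {
      note("error", "empty_stoichiometry", rxns$id[j],
           sprintf("reaction '%s' has empty stoichiometry", rxns$id[j]))
    }
    dangling <- setdiff(names(st), mets$id)
    for (d in dangling) {
      note("error", "dangling_metabolite", rxns$id[j],
           sprintf("reaction '%s' references unknown metabolite '%s'",
                   rxns$id[j], d))
    }
    used <- c(used, names(st))
    if (rxns$lower_bound[j] > rxns$upper_bound[j]) {
      note("error", "inverted_bounds", rxns$id[j],
           sprintf("reaction '%s' has lower_bound %g > upper_bound %g",
                   rxns$id[j], rxns$lower_bound[j], rxns$upper_bound[j]))
    }
    if (rxns$is_exchange[j] && length(st) != 1L) {
      note("error", "exchange_arity", rxns$id[j],
           sprintf("exchange reaction '%s' touches %d metabolites",
                   rxns$id[j], length(st)))
    }
  }
  if (!model$objective %in% rxns$id) {
    note("error", "missing_objective", model$objective,
         sprintf("objective reaction '%s' does not exist", model$objective))
  }
  orphan <- setdiff(mets$id, unique(used))
  for (o in orphan) {
    note("warning", "orphan_metabolite", o,
         sprintf("metabolite '%s' participates in no reaction", o))
  }
  if (length(out) == 0L) {
    tibble(level = character(0), code = character(0), id = character(0),
           message = character(0))
  } else {
    bind_rows(out)
  }
}

stop_on_invalid <- function(model) {
  diag <- validate_model(model)
  err <- diag[diag$level == "error", ]
  if (nrow(err) > 0L) {
    abort(paste0("invalid model:\n", paste("-", err$message, collapse = "\n")))
  }
  invisible(model)
}

#' Metabolite ids internal to the model (not touched by any exchange)
#'
#' @param model A [stoich_model()].
#' @return Character vector of metabolite ids not connected to a boundary
#'   exchange reaction.
#' @export
internal_metabolites <- function(model) {
  exch <- model$reactions$stoichiometry[model$reactions$is_exchange]
  touched <- unique(unlist(lapply(exch, names)))
  setdiff(model$metabolites$id, touched)
}
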