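#' Build a model curation recipe
#'
#' A curation recipe records the three edit classes applied to a published
#' genome-scale model before scenario analysis: reversibility changes
#' (new bound pairs), deactivations (bounds forced to zero), and addition of
#' transport reactions (e.g. for cofactor utilization). Edits are applied in
#' that order by [apply_curation()].
#'
#' @param reversibility A data frame with columns `id`, `lower_bound`,
#'   `upper_bound`, or `NULL`.
#' @param deactivate Character vector of reaction ids to block, or `NULL`.
#' @param add_transport A data frame shaped like `model$reactions`
#'   (columns `id`, `stoichiometry` list column, `lower_bound`,
#'   `upper_bound`), or `NULL`.
#' @return An object of class `curation_recipe`.
#' @export
curation_recipe <- function(reversibility = NULL, deactivate = NULL,
                            add_transport = NULL) {
  empty_rev <- tibble(id = character(0), lower_bound = numeric(0),
                      upper_bound = numeric(0))
  empty_add <- tibble(id = character(0), stoichiometry = list(),
                      lower_bound = numeric(0), upper_bound = numeric(0))
  structure(
    list(
      reversibility = if (is.null(reversibility)) empty_rev else as_tibble(reversibility),
      deactivate = deactivate %||% character(0),
      add_transport = if (is.null(add_transport)) empty_add else as_tibble(add_transport)
    ),
    class = "curation_recipe"
  )
}

#' Read a curation recipe from YAML
#'
#' The YAML file has three optional sections: `reversibility` (list of
#' `{id, lower_bound, upper_bound}`), `deactivate` (list of reaction ids) and
#' `add_transport` (list of `{id, metabolites: {met: coeff, ...}, lower_bound,
#' upper_bound}`).
#'
#' @param path Path to the YAML recipe.
#' @return A [curation_recipe()].
#' @export
read_curation_recipe <- function(path) {
  doc <- yaml::read_yaml(path)
  rev <- if (length(doc$reversibility)) {
    bind_rows(lapply(doc$reversibility, function(x) {
      tibble(id = x$id, lower_bound = as.numeric(x$lower_bound),
             upper_bound = as.numeric(x$upper_bound))
    }))
  }
  add <- if (length(doc$add_transport)) {
    bind_rows(lapply(doc$add_transport, function(x) {
      tibble(id = x$id,
             stoichiometry = list(unlist(x$metabolites)),
             lower_bound = as.numeric(x$lower_bound %||% 0),
             upper_bound = as.numeric(x$upper_bound %||% 1000))
    }))
  }
  curation_recipe(reversibility = rev,
                  deactivate = unlist(doc$deactivate),
                  add_transport = add)
}

#' Apply a curation recipe to a model
#'
#' Applies, in order: reversibility edits, deactivations (bounds set to
#' (0, 0)), then transport-reaction additions. The input model is never
#' modified; applying the same recipe twice gives identical results.
#'
#' @param model A [stoich_model()].
#' @param recipe A [curation_recipe()].
#' @return The curated model.
#' @export
apply_curation <- function(model, recipe) {
  stopifnot(inherits(recipe, "curation_recipe"))
  rev <- recipe$reversibility
  missing <- setdiff(c(rev$id, recipe$deactivate), model$reactions$id)
  if (length(missing)) {
    abort(sprintf("curation recipe references unknown reaction(s): %s",
                  paste(unique(missing), collapse = ", ")))
  }
  dup <- intersect(recipe$add_transport$id, model$reactions$id)
  if (length(dup)) {
    abort(sprintf("curation recipe adds reaction(s) with existing id(s): %s",
                  paste(dup, collapse = ", ")))
  }
  for (i in seq_len(nrow(rev))) {
    model <- set_bounds(model, rev$id[i], rev$lower_bound[i], rev$upper_bound[i])
  }
  for (id in recipe$deactivate) {
    model <- set_bounds(model, id, 0, 0)
  }
  add <- recipe$add_transport
  if (nrow(add)) {
    if (!"name" %in% names(add)) add$name <- add$id
    if (!"subsystem" %in% names(add)) add$subsystem <- NA_character_
    add$is_exchange <- vapply(add$stoichiometry, length, 1L) == 1L
    add <- add[, names(model$reactions)]
    model$reactions <- bind_rows(model$reactions, add)
  }
  stop_on_invalid(model)
  model
}
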