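#' Measured exchange rates for one strain
#'
#' Exponential-phase uptake/secretion rates (mmol gDCW^-1 h^-1) and the
#' measured specific growth rate (h^-1) for one strain. Glucose uptake is
#' negative by the exchange sign convention; the three secretion rates are
#' non-negative.
#'
#' @param strain Strain label.
#' @param glucose Glucose uptake rate (must be negative).
#' @param ethanol,acetate,glycerol Secretion rates (non-negative).
#' @param growth_rate Measured growth rate, h^-1 (non-negative); used for
#'   validation of the FBA prediction, never as a constraint.
#' @return A list of class `measured_rates`.
#' @export
measured_rates <- function(strain, glucose, ethanol, acetate, glycerol,
                           growth_rate) {
  if (glucose >= 0) abort("glucose uptake must be negative (uptake convention)")
  if (growth_rate < 0) abort("growth rate must be non-negative")
  if (any(c(ethanol, acetate, glycerol) < 0)) {
    abort("secretion rates must be non-negative")
  }
  structure(list(strain = strain, glucose = glucose, ethanol = ethanol,
                 acetate = acetate, glycerol = glycerol,
                 growth_rate = growth_rate),
            class = "measured_rates")
}

#' Read measured rates from TSV
#'
#' Expects columns `strain`, `glucose`, `ethanol`, `acetate`, `glycerol`,
#' `growth_rate`, one row per strain.
#'
#' @param path TSV path.
#' @return A tibble; convert a row with [as_measured_rates()].
#' @export
read_rates_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Coerce a one-row data frame to measured_rates
#'
#' @param x A one-row data frame with the [measured_rates()] columns, or a
#'   `measured_rates` object (returned unchanged).
#' @return A [measured_rates()] object.
#' @export
as_measured_rates <- function(x) {
  if (inherits(x, "measured_rates")) return(x)
  stopifnot(is.data.frame(x), nrow(x) == 1L)
  measured_rates(x$strain, x$glucose, x$ethanol, x$acetate, x$glycerol,
                 x$growth_rate)
}

default_exchange_map <- function() {
  c(glucose = "EX_glc", ethanol = "EX_etoh", acetate = "EX_ac",
    glycerol = "EX_glyc")
}

#' Fix exchange bounds to measured rates
#'
#' Fixes the bounds of the glucose, ethanol, acetate and glycerol exchange
#' reactions to the measured values (lower = upper = rate), enforcing the
#' sign convention (negative = uptake). All other exchange reactions are left
#' untouched.
#'
#' @param model A [stoich_model()].
#' @param rates A [measured_rates()] (or one-row data frame).
#' @param exchange_map Named character vector mapping metabolite names
#'   (`glucose`, `ethanol`, `acetate`, `glycerol`) to exchange reaction ids.
#' @return The constrained model.
#' @export
apply_exchange_constraints <- function(model, rates,
                                       exchange_map = default_exchange_map()) {
  rates <- as_measured_rates(rates)
  for (met in c("glucose", "ethanol", "acetate", "glycerol")) {
    id <- unname(exchange_map[met])
    if (is.null(id) || is.na(id)) {
      abort(sprintf("no exchange reaction mapped for metabolite '%s'", met))
    }
    if (!id %in% model$reactions$id) {
      abort(sprintf("exchange reaction '%s' for metabolite '%s' not in model",
                    id, met))
    }
    model <- set_bounds(model, id, rates[[met]], rates[[met]])
  }
  model
}

#' Build a constraint directive
#'
#' A directive adjusts the bounds of one reaction on the per-100-glucose
#' scale; [run_scenario()] rescales it to raw units using the measured
#' glucose uptake before solving. `fix` sets both bounds to `value`;
#' `lower_bound`/`upper_bound` override one bound; `fold_of_reference`
#' scales a control-strain reference flux by `value` and constrains the flux
#' away from zero in the reference direction (lower bound for positive
#' reference, upper bound for negative reference).
#'
#' @param reaction Reaction id.
#' @param kind One of `"fix"`, `"lower_bound"`, `"upper_bound"`,
#'   `"fold_of_reference"`.
#' @param value Bound value (per 100 glucose), or the fold for
#'   `fold_of_reference`.
#' @param reference_flux Control-strain flux (per 100 glucose); required for
#'   `fold_of_reference`.
#' @param source Free-text provenance tag (e.g. `"transcriptomic"`,
#'   `"diffusion"`).
#' @return A one-row directive tibble.
#' @export
constraint_directive <- function(reaction,
                                 kind = c("fix", "lower_bound", "upper_bound",
                                          "fold_of_reference"),
                                 value, reference_flux = NA_real_,
                                 source = NA_character_) {
  kind <- match.arg(kind)
  if (kind == "fold_of_reference" && is.na(reference_flux)) {
    abort("fold_of_reference directives require reference_flux")
  }
  tibble(reaction = reaction, kind = kind, value = as.numeric(value),
         reference_flux = as.numeric(reference_flux), source = source)
}

empty_directives <- function() {
  tibble(reaction = character(0), kind = character(0), value = numeric(0),
         reference_flux = numeric(0), source = character(0))
}

#' Derive flux-bound directives from transcriptomic fold changes
#'
#' Formalizes the transcriptome-to-flux constraint rule: for each reaction
#' with a measured expression fold change, the constraint is calculated from
#' the control-strain flux. Up-regulated reactions receive a lower bound at
#' `fold x control flux` (the flux direction is preserved: for a negative
#' control flux the bound is an upper bound at the more-negative value);
#' down-regulated reactions receive the corresponding upper (or lower) bound.
#' A reaction whose control flux is zero cannot be scaled; it is flagged
#' unresolvable with a warning and excluded from the usable directives.
#'
#' @param control_fluxes A normalized (per-100-glucose) `flux_distribution`
#'   of the control strain.
#' @param table A data frame with columns `reaction`, `fold`, `direction`
#'   (`"up"` or `"down"`).
#' @return A directive tibble (see [constraint_directive()]) with an extra
#'   logical column `resolvable`.
#' @export
derive_transcriptomic_constraints <- function(control_fluxes, table) {
  stopifnot(inherits(control_fluxes, "flux_distribution"))
  if (control_fluxes$basis != "per_100_glucose") {
    abort("control fluxes must be normalized per 100 glucose units")
  }
  table <- as_tibble(table)
  missing <- setdiff(table$reaction, names(control_fluxes$fluxes))
  if (length(missing)) {
    abort(sprintf("transcriptomic table references unknown reaction(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- lapply(seq_len(nrow(table)), function(i) {
    rid <- table$reaction[i]
    fold <- table$fold[i]
    dirn <- match.arg(table$direction[i], c("up", "down"))
    ref <- control_fluxes$fluxes[[rid]]
    if (abs(ref) < 1e-9) {
      warn(sprintf(
        "control flux of '%s' is zero: cannot scale a zero flux, directive flagged unresolvable",
        rid))
      d <- constraint_directive(rid, "fold_of_reference", fold,
                                reference_flux = 0, source = "transcriptomic")
      d$resolvable <- FALSE
      return(d)
    }
    bound <- fold * ref
    kind <- if (dirn == "up") {
      if (ref >= 0) "lower_bound" else "upper_bound"
    } else {
      if (ref >= 0) "upper_bound" else "lower_bound"
    }
    d <- constraint_directive(rid, kind, bound, reference_flux = ref,
                              source = "transcriptomic")
    d$resolvable <- TRUE
    d
  })
  bind_rows(out)
}

#' Define a constraint scenario
#'
#' A scenario bundles the measured exchange rates, the transaldolase lower
#' bound, the ordered constraint directives and the reaction ids needed for
#' reporting. Directives are applied after the rates and the transaldolase
#' bound, in list order; all directive values are on the per-100-glucose
#' scale.
#'
#' @param name Scenario name (unique within a run).
#' @param rates A [measured_rates()].
#' @param directives A directive tibble ([constraint_directive()] rows bound
#'   together), or `NULL`.
#' @param tala_lower_bound Lower bound on the transaldolase reaction, per 100
#'   glucose units (default 11); `NULL` to skip.
#' @param tala_reaction Transaldolase reaction id.
#' @param isoprenoid_reaction Reaction whose flux is reported as the
#'   isoprenoid (mevalonate) pathway flux.
#' @param biomass_reaction Objective override; `NULL` keeps the model's
#'   objective.
#' @param exchange_map See [apply_exchange_constraints()].
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(name, rates, directives = NULL,
                          tala_lower_bound = 11, tala_reaction = "TALA",
                          isoprenoid_reaction = "HMGCOAR",
                          biomass_reaction = NULL,
                          exchange_map = default_exchange_map()) {
  rates <- as_measured_rates(rates)
  directives <- if (is.null(directives)) empty_directives() else as_tibble(directives)
  structure(
    list(name = name, rates = rates, directives = directives,
         tala_lower_bound = tala_lower_bound, tala_reaction = tala_reaction,
         isoprenoid_reaction = isoprenoid_reaction,
         biomass_reaction = biomass_reaction, exchange_map = exchange_map,
         target_provenance = NULL),
    class = "scenario_spec"
  )
}

#' Fix the isoprenoid target flux chosen from an experimental fold change
#'
#' Appends a `fix` directive on the scenario's isoprenoid reaction at
#' `chosen_value` (per 100 glucose) and records the control-strain capacity
#' and the experimental fold change as provenance. The chosen value is an
#' explicit parameter: the mapping from (capacity, fold) to the fixed flux is
#' a modelling decision, not an arithmetic one. If the chosen value exceeds
#' the attainable capacity under the scenario constraints the infeasibility
#' surfaces at solve time; a warning pre-flags it here when a capacity is
#' supplied.
#'
#' @param spec A [scenario_spec()].
#' @param control_capacity Maximum isoprenoid flux of the control strain
#'   (per 100 glucose), from [maximize_reaction_flux()].
#' @param fold Experimentally observed isoprenoid fold change (must be > 0).
#' @param chosen_value Flux value to fix (per 100 glucose).
#' @param scenario_capacity Optional maximum isoprenoid flux attainable under
#'   this scenario's constraints (per 100 glucose), from
#'   [maximize_reaction_flux()] on the constrained model; when supplied, a
#'   chosen value above it is pre-flagged with a warning.
#' @return The updated `scenario_spec`.
#' @export
set_target_flux_from_fold_change <- function(spec, control_capacity, fold,
                                             chosen_value,
                                             scenario_capacity = NA_real_) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (fold <= 0) abort("fold change must be positive")
  if (!is.na(scenario_capacity) && chosen_value > scenario_capacity + 1e-9) {
    warn(sprintf(
      "chosen isoprenoid flux %.3g exceeds the attainable capacity %.3g under this scenario; the solve will be infeasible",
      chosen_value, scenario_capacity))
  }
  d <- constraint_directive(spec$isoprenoid_reaction, "fix", chosen_value,
                            source = "target_fix")
  d$resolvable <- TRUE
  if (!"resolvable" %in% names(spec$directives) && nrow(spec$directives)) {
    spec$directives$resolvable <- TRUE
  }
  spec$directives <- bind_rows(spec$directives, d)
  spec$target_provenance <- list(control_capacity = control_capacity,
                                 fold = fold, chosen_value = chosen_value)
  spec
}

apply_directive <- function(model, reaction, kind, value, reference_flux,
                            scale) {
  if (kind == "fold_of_reference") {
    bound <- value * reference_flux * scale
    if (bound >= 0) {
      return(set_bounds(model, reaction, lower_bound = bound))
    }
    return(set_bounds(model, reaction, upper_bound = bound))
  }
  raw <- value * scale
  switch(kind,
    fix = set_bounds(model, reaction, raw, raw),
    lower_bound = set_bounds(model, reaction, lower_bound = raw),
    upper_bound = set_bounds(model, reaction, upper_bound = raw),
    abort(sprintf("unknown directive kind '%s'", kind))
  )
}

constrain_model <- function(model, spec) {
  model <- apply_exchange_constraints(model, spec$rates, spec$exchange_map)
  if (!is.null(spec$biomass_reaction)) {
    rxn_row(model, spec$biomass_reaction)
    model$objective <- spec$biomass_reaction
  }
  scale <- abs(spec$rates$glucose) / 100  # per-100-glucose -> raw units
  if (!is.null(spec$tala_lower_bound) && !is.null(spec$tala_reaction)) {
    model <- set_bounds(model, spec$tala_reaction,
                        lower_bound = spec$tala_lower_bound * scale)
  }
  dirs <- spec$directives
  for (i in seq_len(nrow(dirs))) {
    if ("resolvable" %in% names(dirs) && isFALSE(dirs$resolvable[i])) next
    model <- apply_directive(model, dirs$reaction[i], dirs$kind[i],
                             dirs$value[i], dirs$reference_flux[i], scale)
  }
  model
}

#' Run one constraint scenario
#'
#' Applies, in order: the measured exchange rates, the transaldolase lower
#' bound, then every directive; solves with biomass maximization and
#' parsimonious refinement; normalizes fluxes to 100 glucose units; and
#' reports predicted vs measured growth, the isoprenoid pathway flux and its
#' capacity. Infeasible scenarios are returned with status `"infeasible"`
#' and a constraint report in which each directive is marked `binding` if
#' removing it alone restores feasibility.
#'
#' @param model A curated [stoich_model()].
#' @param spec A [scenario_spec()].
#' @param parsimonious Use parsimonious refinement for the reported fluxes.
#' @return A list of class `scenario_result` with elements `name`, `status`,
#'   `dist` (normalized `flux_distribution`), `growth` (one-row tibble,
#'   predicted vs measured), `isoprenoid_flux` and `isoprenoid_capacity`
#'   (per 100 glucose), and `constraint_report`.
#' @export
#' @examples
#' toy <- generate_toy_model(toy_model_spec())
#' res <- run_scenario(toy, toy_scenarios(toy)$control)
#' glance(res)
run_scenario <- function(model, spec, parsimonious = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"))
  constrained <- constrain_model(model, spec)
  glc_id <- spec$exchange_map[["glucose"]]
  scale <- abs(spec$rates$glucose) / 100
  dist <- solve_fba(constrained, parsimonious = parsimonious,
                    glucose_exchange = glc_id)

  report <- spec$directives
  if (nrow(report)) report$binding <- NA
  capacity <- NA_real_
  iso_flux <- NA_real_
  growth <- tibble(strain = spec$rates$strain,
                   predicted = NA_real_,
                   measured = spec$rates$growth_rate,
                   ratio = NA_real_)

  if (dist$status == "optimal") {
    dist <- normalize_fluxes(dist, glc_id)
    growth$predicted <- dist$objective_value
    growth$ratio <- growth$predicted / growth$measured
    if (spec$isoprenoid_reaction %in% names(dist$fluxes)) {
      iso_flux <- dist$fluxes[[spec$isoprenoid_reaction]]
      capacity <- tryCatch(
        maximize_reaction_flux(constrained, spec$isoprenoid_reaction) / scale,
        isoflux_infeasible = function(e) NA_real_
      )
    }
  } else if (nrow(report)) {
    # leave-one-out diagnosis of which directives make the scenario infeasible
    for (i in seq_len(nrow(report))) {
      sub <- spec
      sub$directives <- spec$directives[-i, , drop = FALSE]
      sub_dist <- solve_fba(constrain_model(model, sub), parsimonious = FALSE,
                            glucose_exchange = glc_id)
      report$binding[i] <- sub_dist$status == "optimal"
    }
  }
  structure(
    list(name = spec$name, spec = spec, status = dist$status, dist = dist,
         growth = growth, isoprenoid_flux = iso_flux,
         isoprenoid_capacity = capacity, constraint_report = report),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s: %s\n", x$name, x$status))
  if (x$status == "optimal") {
    cat(sprintf("  growth predicted %.4g vs measured %.4g\n",
                x$growth$predicted, x$growth$measured))
    cat(sprintf("  isoprenoid flux %.4g (capacity %.4g) per 100 glucose\n",
                x$isoprenoid_flux, x$isoprenoid_capacity))
  } else if (nrow(x$constraint_report)) {
    b <- x$constraint_report$reaction[isTRUE(x$constraint_report$binding) |
                                        x$constraint_report$binding %in% TRUE]
    if (length(b)) cat(sprintf("  binding directive(s): %s\n",
                               paste(b, collapse = ", ")))
  }
  invisible(x)
}

#' @rdname run_scenario
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @method tidy scenario_result
#' @export
tidy.scenario_result <- function(x, ...) {
  tidy(x$dist)
}

#' @rdname run_scenario
#' @method glance scenario_result
#' @export
glance.scenario_result <- function(x, ...) {
  tibble(name = x$name, status = x$status,
         growth_predicted = x$growth$predicted,
         growth_measured = x$growth$measured,
         isoprenoid_flux = x$isoprenoid_flux,
         isoprenoid_capacity = x$isoprenoid_capacity)
}

#' Run a set of scenarios and summarise them
#'
#' @param model A curated [stoich_model()].
#' @param specs A (named) list of [scenario_spec()] objects.
#' @param parsimonious Use parsimonious refinement.
#' @return A tibble with one row per scenario (the [glance.scenario_result()]
#'   columns) and a `result` list column holding the full results.
#' @export
run_scenarios <- function(model, specs, parsimonious = TRUE) {
  nm <- vapply(specs, function(s) s$name, "")
  if (anyDuplicated(nm)) abort("scenario names must be unique within a run")
  results <- lapply(specs, function(s) run_scenario(model, s, parsimonious))
  out <- bind_rows(lapply(results, glance))
  out$result <- results
  out
}

#' Read a scenario from YAML
#'
#' The YAML file holds a `rates:` block (`strain`, `glucose`, `ethanol`,
#' `acetate`, `glycerol`, `growth_rate`), optional `tala_lower_bound`,
#' `isoprenoid_reaction`, `biomass_reaction`, `exchange_map`, and a
#' `directives:` list of `{reaction, kind, value, reference_flux, source}`
#' entries (values per 100 glucose).
#'
#' @param path YAML path.
#' @return A [scenario_spec()].
#' @export
read_scenario_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  rates <- do.call(measured_rates, doc$rates)
  dirs <- if (length(doc$directives)) {
    bind_rows(lapply(doc$directives, function(d) {
      constraint_directive(d$reaction, d$kind, d$value,
                           reference_flux = d$reference_flux %||% NA_real_,
                           source = d$source %||% "file")
    }))
  }
  em <- if (!is.null(doc$exchange_map)) unlist(doc$exchange_map) else default_exchange_map()
  scenario_spec(
    name = doc$name %||% sub("\\.ya?ml$", "", basename(path)),
    rates = rates, directives = dirs,
    tala_lower_bound = doc$tala_lower_bound %||% 11,
    tala_reaction = doc$tala_reaction %||% "TALA",
    isoprenoid_reaction = doc$isoprenoid_reaction %||% "HMGCOAR",
    biomass_reaction = doc$biomass_reaction,
    exchange_map = em
  )
}

#' The five packaged toy scenarios
#'
#' Assembles the packaged scenario set for the toy central-carbon model:
#' `control`, `mutant`, `mutant_transcriptomic`, `mutant_high_phosphate` and
#' `mutant_pdh_test`. The control scenario is solved first and its normalized
#' fluxes are used to derive the transcriptomic directives from the packaged
#' fold-change table ([derive_transcriptomic_constraints()]); the
#' transport/diffusion directives and the isoprenoid target fix come from the
#' packaged scenario files. The PDH-test scenario adds a forced pyruvate
#' dehydrogenase flux on top of the transcriptomic constraints; with the
#' mitochondrial pyruvate transport cap in place it is infeasible by
#' construction.
#'
#' @param model The toy model the scenarios will run on (used to solve the
#'   control scenario when deriving transcriptomic bounds).
#' @param parsimonious Parsimonious refinement for the control solve.
#' @return A named list of five [scenario_spec()] objects.
#' @export
toy_scenarios <- function(model = generate_toy_model(toy_model_spec()),
                          parsimonious = TRUE) {
  sc_dir <- system.file("extdata", "scenarios", package = "isoflux")
  load_sc <- function(nm) read_scenario_yaml(file.path(sc_dir, paste0("toy_", nm, ".yaml")))
  control <- load_sc("control")
  mutant <- load_sc("mutant")
  transcriptomic <- load_sc("mutant_transcriptomic")
  high_pi <- load_sc("mutant_high_phosphate")
  pdh <- load_sc("mutant_pdh_test")

  ctrl_res <- run_scenario(model, control, parsimonious = parsimonious)
  if (ctrl_res$status != "optimal") {
    abort("control scenario is not optimal on this model; cannot derive transcriptomic constraints")
  }
  tab <- readr::read_tsv(system.file("extdata", "toy_transcriptomic_constraints.tsv",
                                     package = "isoflux"), show_col_types = FALSE)
  derived <- derive_transcriptomic_constraints(ctrl_res$dist, tab)
  for (nm in c("mutant_transcriptomic", "mutant_high_phosphate", "mutant_pdh_test")) {
    sc <- switch(nm, mutant_transcriptomic = transcriptomic,
                 mutant_high_phosphate = high_pi, mutant_pdh_test = pdh)
    base <- sc$directives
    if (nrow(base) && !"resolvable" %in% names(base)) base$resolvable <- TRUE
    sc$directives <- bind_rows(derived, base)
    assign(nm, sc)
  }
  list(control = control, mutant = mutant,
       mutant_transcriptomic = mutant_transcriptomic,
       mutant_high_phosphate = mutant_high_phosphate,
       mutant_pdh_test = mutant_pdh_test)
}
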