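# The LP core lives in lp.R (bounded-variable two-phase simplex).

new_flux_distribution <- function(fluxes, objective_value, status,
                                  basis = "raw", glucose_exchange = NA_character_,
                                  parsimonious = FALSE) {
  structure(
    list(fluxes = fluxes, objective_value = objective_value, status = status,
         basis = basis, glucose_exchange = glucose_exchange,
         parsimonious = parsimonious),
    class = "flux_distribution"
  )
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution> status: %s\n", x$status))
  if (x$status == "optimal") {
    cat(sprintf("  objective: %.6g  basis: %s  parsimonious: %s\n",
                x$objective_value, x$basis, x$parsimonious))
    cat(sprintf("  %d reaction fluxes (%d above 1e-6)\n", length(x$fluxes),
                sum(abs(x$fluxes) > 1e-6)))
  }
  invisible(x)
}

#' Turn a flux distribution into a tibble
#'
#' @param x A `flux_distribution` from [solve_fba()].
#' @param ... Unused.
#' @return A tibble with columns `reaction` and `flux`, empty when the solve
#'   was not optimal.
#' @method tidy flux_distribution
#' @export
tidy.flux_distribution <- function(x, ...) {
  tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}

#' One-row summary of a flux distribution
#'
#' @param x A `flux_distribution`.
#' @param ... Unused.
#' @return A one-row tibble with `status`, `objective_value`, `basis`,
#'   `parsimonious` and `glucose_exchange`.
#' @method glance flux_distribution
#' @export
glance.flux_distribution <- function(x, ...) {
  tibble(status = x$status, objective_value = x$objective_value,
         basis = x$basis, parsimonious = x$parsimonious,
         glucose_exchange = x$glucose_exchange)
}

# Validate for solving: structural errors abort, inverted bounds make the
# LP infeasible (a deactivated reaction forced by a directive must surface
# as status "infeasible", not as an exception).
check_solvable <- function(model) {
  diag <- validate_model(model)
  err <- diag[diag$level == "error" & diag$code != "inverted_bounds", ]
  if (nrow(err) > 0L) {
    abort(paste0("invalid model:\n", paste("-", err$message, collapse = "\n")))
  }
  !any(diag$code == "inverted_bounds")
}

#' Flux balance analysis by biomass (objective) maximization
#'
#' Solves the FBA linear program: maximize the objective reaction flux
#' subject to the steady-state constraint S v = 0 and the flux bounds
#' lb <= v <= ub. With `parsimonious = TRUE` a second linear program is
#' solved among the objective-optimal solutions, minimizing the total
#' absolute flux sum |v| with the objective fixed at its optimum
#' (flux splitting into nonnegative forward/reverse parts keeps this
#' linear). Parsimonious refinement yields a deterministic representative
#' solution under alternate optima and is used for all reported per-reaction
#' fluxes.
#'
#' Infeasibility is reported through the `status` field of the result, never
#' through silent zeros.
#'
#' @param model A [stoich_model()].
#' @param parsimonious Refine the solution by total-flux minimization at the
#'   fixed optimal objective value.
#' @param glucose_exchange Optional id of the glucose exchange reaction,
#'   recorded for later normalization with [normalize_fluxes()].
#' @return A `flux_distribution`: fields `fluxes` (named vector; empty unless
#'   status is `"optimal"`), `objective_value`, `status`, `basis` (`"raw"`),
#'   `glucose_exchange`, `parsimonious`.
#' @export
#' @examples
#' toy <- generate_toy_model(toy_model_spec())
#' sol <- solve_fba(toy, parsimonious = TRUE, glucose_exchange = "EX_glc")
#' glance(sol)
solve_fba <- function(model, parsimonious = FALSE, glucose_exchange = NA_character_) {
  if (!check_solvable(model)) {
    return(new_flux_distribution(setNames(numeric(0), character(0)), NA_real_,
                                 "infeasible", glucose_exchange = glucose_exchange))
  }
  S <- as.matrix(stoichiometric_matrix(model))
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  obj <- as.numeric(model$reactions$id == model$objective)
  res <- lp_max(obj, lb, ub, eq = list(A = S, b = rep(0, nrow(S))))
  if (res$status != "optimal") {
    return(new_flux_distribution(setNames(numeric(0), character(0)), NA_real_,
                                 res$status, glucose_exchange = glucose_exchange))
  }
  v <- res$solution
  zstar <- res$value
  if (parsimonious) {
    v <- pfba_refine(S, lb, ub, obj, zstar) %||% v
  }
  names(v) <- model$reactions$id
  new_flux_distribution(v, zstar, "optimal",
                        glucose_exchange = glucose_exchange,
                        parsimonious = parsimonious)
}

# Minimize sum |v| subject to S v = 0, lb <= v <= ub, obj'v >= zstar - tol.
# Variables x = (p, q), v = p - q, p, q >= 0.
pfba_refine <- function(S, lb, ub, obj, zstar, tol = 1e-9) {
  n <- ncol(S)
  pu <- pmax(ub, 0); qu <- pmax(-lb, 0)
  cc <- rep(-1, 2 * n)  # maximize -(sum p + sum q)
  Spq <- cbind(S, -S)
  ge <- list(A = matrix(c(obj, -obj), nrow = 1), b = zstar - tol)
  # p - q must respect bounds not implied by the part bounds
  extra_ge <- which(lb > 0)
  extra_le <- which(ub < 0)
  if (length(extra_ge)) {
    rows <- matrix(0, length(extra_ge), 2 * n)
    for (k in seq_along(extra_ge)) {
      j <- extra_ge[k]; rows[k, j] <- 1; rows[k, n + j] <- -1
    }
    ge$A <- rbind(ge$A, rows); ge$b <- c(ge$b, lb[extra_ge])
  }
  le <- NULL
  if (length(extra_le)) {
    rows <- matrix(0, length(extra_le), 2 * n)
    for (k in seq_along(extra_le)) {
      j <- extra_le[k]; rows[k, j] <- 1; rows[k, n + j] <- -1
    }
    le <- list(A = rows, b = ub[extra_le])
  }
  res <- lp_max(cc, lb = rep(0, 2 * n), ub = c(pu, qu),
                eq = list(A = Spq, b = rep(0, nrow(S))), ge = ge, le = le)
  if (res$status != "optimal") return(NULL)
  res$solution[seq_len(n)] - res$solution[n + seq_len(n)]
}

#' Maximum attainable flux of one reaction
#'
#' Computes the flux capacity of a target reaction under all current model
#' constraints by maximizing its flux as the linear-programming objective
#' (the biomass objective is ignored for this solve). The optimal value is
#' unique even when the optimal flux vector is degenerate.
#'
#' @param model A [stoich_model()].
#' @param target Reaction id to maximize.
#' @return The maximum flux (a scalar).
#' @export
maximize_reaction_flux <- function(model, target) {
  rxn_row(model, target)
  if (!check_solvable(model)) {
    abort("flux capacity undefined: constraint set is infeasible",
          class = "isoflux_infeasible")
  }
  S <- as.matrix(stoichiometric_matrix(model))
  obj <- as.numeric(model$reactions$id == target)
  res <- lp_max(obj, model$reactions$lower_bound, model$reactions$upper_bound,
                eq = list(A = S, b = rep(0, nrow(S))))
  if (res$status != "optimal") {
    abort(sprintf("flux capacity undefined: constraint set is %s", res$status),
          class = "isoflux_infeasible")
  }
  res$value
}

#' Normalize a flux distribution to 100 units of glucose
#'
#' Rescales every flux by `100 / |glucose exchange flux|` so that the glucose
#' uptake magnitude equals 100, the reporting convention used for all scenario
#' outputs. Idempotent on an already-normalized distribution. The LP objective
#' value (`objective_value`) is kept on the raw scale; the normalized biomass
#' flux is available from the fluxes themselves.
#'
#' @param dist A `flux_distribution` with status `"optimal"`.
#' @param glucose_exchange Glucose exchange reaction id; defaults to the id
#'   recorded in `dist`.
#' @return The normalized `flux_distribution` (basis `"per_100_glucose"`).
#' @export
normalize_fluxes <- function(dist, glucose_exchange = NULL) {
  stopifnot(inherits(dist, "flux_distribution"))
  if (dist$status != "optimal") {
    abort("cannot normalize a non-optimal flux distribution")
  }
  if (dist$basis == "per_100_glucose") return(dist)
  glc <- glucose_exchange %||% dist$glucose_exchange
  if (is.na(glc) || !glc %in% names(dist$fluxes)) {
    abort("glucose exchange reaction id is not set or not in the distribution")
  }
  g <- dist$fluxes[[glc]]
  if (abs(g) < 1e-12) {
    abort("glucose exchange flux is zero: normalization basis undefined")
  }
  dist$fluxes <- dist$fluxes * (100 / abs(g))
  dist$basis <- "per_100_glucose"
  dist$glucose_exchange <- glc
  dist
}

#' Steady-state mass-balance residuals of a solved distribution
#'
#' For each metabolite, the residual is the net production
#' `sum_r coeff(m, r) * v_r`. For metabolites internal to the network the
#' residual of a feasible LP solution is zero to solver tolerance; metabolites
#' touched by an exchange reaction are flagged so boundary throughput is not
#' mistaken for imbalance.
#'
#' @param model The [stoich_model()] that produced `dist`.
#' @param dist An optimal `flux_distribution` (raw or normalized).
#' @return A tibble with columns `metabolite`, `compartment`, `residual`,
#'   `has_exchange`.
#' @export
mass_balance_residual <- function(model, dist) {
  stopifnot(inherits(dist, "flux_distribution"))
  if (dist$status != "optimal" || length(dist$fluxes) == 0L) {
    abort("mass balance undefined: distribution has no fluxes (non-optimal solve)")
  }
  S <- stoichiometric_matrix(model)
  v <- dist$fluxes[colnames(S)]
  r <- as.numeric(S %*% v)
  internal <- internal_metabolites(model)
  tibble(metabolite = rownames(S),
         compartment = model$metabolites$compartment,
         residual = r,
         has_exchange = !rownames(S) %in% internal)
}

#' Write a flux distribution to TSV
#'
#' Emits a comment header block (`# status`, `# objective`, `# basis`,
#' `# glucose_exchange`) followed by two columns, `reaction_id` and `flux`.
#'
#' @param dist A `flux_distribution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(dist, path) {
  hdr <- c(sprintf("# status\t%s", dist$status),
           sprintf("# objective\t%.12g", dist$objective_value),
           sprintf("# basis\t%s", dist$basis),
           sprintf("# glucose_exchange\t%s", dist$glucose_exchange))
  writeLines(c(hdr, "reaction_id\tflux"), path)
  if (length(dist$fluxes)) {
    write(sprintf("%s\t%.12g", names(dist$fluxes), dist$fluxes),
          file = path, append = TRUE)
  }
  invisible(path)
}
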