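#' Parameters for the synthetic central-carbon toy model
#'
#' The toy model emulates, at lumped-pathway resolution, the compartmentalized
#' yeast network the scenario pipeline is designed for: glycolysis, a pentose
#' phosphate shunt (transaldolase proxy `TALA`), the cytosolic pyruvate
#' decarboxylase bypass (pyruvate -> acetaldehyde -> acetate -> mitochondrial
#' acetyl-CoA, with an explicit ATP cost at acetyl-CoA synthetase), pyruvate
#' dehydrogenase, a TCA lump whose substrate-level phosphorylation consumes
#' mitochondrial phosphate, an optional glyoxylate shunt that regenerates
#' redox without phosphate, an HMG-CoA reductase / mevalonate sink, ATP
#' synthase driven by mitochondrial NADH and phosphate, and a biomass reaction
#' that retains phosphate (so growth is bounded by phosphate supply by
#' construction).
#'
#' Switching off a module (`include_*` flags) blocks the corresponding
#' reactions by setting their bounds to zero; the reactions stay in the model
#' so scenario directives addressing them surface as infeasibility rather
#' than as missing ids.
#'
#' @param include_glyoxylate Keep the glyoxylate shunt open.
#' @param include_pdc_bypass Keep the PDC/ALDD/ACS bypass open.
#' @param include_mva_sink Keep the HMG-CoA/mevalonate sink open.
#' @param atp_per_acs ATP cost (ATP -> AMP + PPi) per acetyl-CoA made by
#'   acetyl-CoA synthetase.
#' @param phosphate_supply Upper bound on phosphate uptake
#'   (mmol gDCW^-1 h^-1); the phosphate exchange lower bound is its negative.
#' @param seed Integer kept for interface symmetry with the random-model
#'   generator; the toy model is fully deterministic given the other fields.
#' @return A list of class `toy_model_spec`.
#' @export
toy_model_spec <- function(include_glyoxylate = TRUE,
                           include_pdc_bypass = TRUE,
                           include_mva_sink = TRUE,
                           atp_per_acs = 1,
                           phosphate_supply = 2,
                           seed = 1L) {
  stopifnot(atp_per_acs > 0, phosphate_supply >= 0)
  structure(
    list(include_glyoxylate = include_glyoxylate,
         include_pdc_bypass = include_pdc_bypass,
         include_mva_sink = include_mva_sink,
         atp_per_acs = atp_per_acs,
         phosphate_supply = phosphate_supply,
         seed = as.integer(seed)),
    class = "toy_model_spec"
  )
}

#' Generate the compartmentalized central-carbon toy model
#'
#' Builds a three-compartment (extracellular/cytosol/mitochondria)
#' stoichiometric model with the network described in [toy_model_spec()].
#' The model is deterministic given the spec and passes [validate_model()]
#' with zero diagnostics. Designed-in couplings: biomass formation retains
#' phosphate, so a `phosphate_supply` of zero forces a zero biomass optimum;
#' the TCA lump needs mitochondrial phosphate while the glyoxylate shunt does
#' not, so phosphate scarcity reroutes acetyl-CoA oxidation through the
#' shunt; acetyl-CoA synthetase hydrolyses ATP to AMP + PPi, and mitochondrial
#' diphosphatase plus the cytosol-to-mitochondria phosphate transporter are
#' the only mitochondrial phosphate producers.
#'
#' @param spec A [toy_model_spec()].
#' @return A [stoich_model()] with objective `BIOMASS` and glucose exchange
#'   `EX_glc`.
#' @export
generate_toy_model <- function(spec = toy_model_spec()) {
  stopifnot(inherits(spec, "toy_model_spec"))
  a <- spec$atp_per_acs

  mets <- tibble(
    id = c("glc_e", "etoh_e", "ac_e", "glyc_e", "pi_e", "co2_e", "mva_e",
           "glc_c", "pyr_c", "acald_c", "etoh_c", "ac_c", "glyc_c", "atp_c",
           "adp_c", "pi_c", "nadh_c", "nadph_c", "co2_c", "mva_c",
           "pyr_m", "ac_m", "accoa_m", "atp_m", "adp_m", "amp_m", "ppi_m",
           "pi_m", "nadh_m", "co2_m"),
    name = c("glucose", "ethanol", "acetate", "glycerol", "phosphate", "CO2",
             "mevalonate", "glucose", "pyruvate", "acetaldehyde", "ethanol",
             "acetate", "glycerol", "ATP", "ADP", "phosphate", "NADH", "NADPH",
             "CO2", "mevalonate", "pyruvate", "acetate", "acetyl-CoA", "ATP",
             "ADP", "AMP", "diphosphate", "phosphate", "NADH", "CO2"),
    compartment = c(rep("e", 7), rep("c", 13), rep("m", 10))
  )

  rx <- function(id, name, st, lb = 0, ub = 1000, subsystem = NA_character_) {
    tibble(id = id, name = name, stoichiometry = list(st),
           lower_bound = lb, upper_bound = ub, subsystem = subsystem)
  }
  rxns <- bind_rows(
    rx("EX_glc",  "glucose exchange",   c(glc_e = -1), lb = -10, ub = 0),
    rx("EX_etoh", "ethanol exchange",   c(etoh_e = -1)),
    rx("EX_ac",   "acetate exchange",   c(ac_e = -1)),
    rx("EX_glyc", "glycerol exchange",  c(glyc_e = -1)),
    rx("EX_pi",   "phosphate exchange", c(pi_e = -1),
       lb = -spec$phosphate_supply, ub = 1000),
    rx("EX_co2",  "CO2 exchange",       c(co2_e = -1)),
    rx("EX_mva",  "mevalonate sink",    c(mva_e = -1)),
    rx("GLCt",    "glucose transport",  c(glc_e = -1, glc_c = 1), subsystem = "transport"),
    rx("ETOHt",   "ethanol export",     c(etoh_c = -1, etoh_e = 1), subsystem = "transport"),
    rx("ACt_out", "acetate export",     c(ac_c = -1, ac_e = 1), subsystem = "transport"),
    rx("GLYCt",   "glycerol export",    c(glyc_c = -1, glyc_e = 1), subsystem = "transport"),
    rx("PIt_ec",  "phosphate uptake transport", c(pi_e = -1, pi_c = 1), subsystem = "transport"),
    rx("PIt_cm",  "mitochondrial phosphate transporter", c(pi_c = -1, pi_m = 1), subsystem = "transport"),
    rx("CO2t_c",  "cytosolic CO2 export", c(co2_c = -1, co2_e = 1), subsystem = "transport"),
    rx("CO2t_m",  "mitochondrial CO2 export", c(co2_m = -1, co2_e = 1), subsystem = "transport"),
    rx("PYRt_cm", "mitochondrial pyruvate transport", c(pyr_c = -1, pyr_m = 1), subsystem = "transport"),
    rx("ACt_cm",  "mitochondrial acetate transport", c(ac_c = -1, ac_m = 1), subsystem = "transport"),
    rx("MVAt",    "mevalonate export",  c(mva_c = -1, mva_e = 1), subsystem = "transport"),
    rx("NADHSH",  "NADH shuttle",       c(nadh_c = -1, nadh_m = 1), subsystem = "transport"),
    rx("GLYC_L",  "glycolysis (lumped)",
       c(glc_c = -1, adp_c = -2, pi_c = -2, pyr_c = 2, atp_c = 2, nadh_c = 2),
       subsystem = "glycolysis"),
    rx("TALA",    "pentose phosphate shunt (transaldolase proxy)",
       c(glc_c = -1, pyr_c = 1, nadph_c = 2, co2_c = 3), subsystem = "ppp"),
    rx("GLYCS",   "glycerol synthesis",
       c(glc_c = -0.5, nadh_c = -1, glyc_c = 1), subsystem = "glycolysis"),
    rx("PDC",     "pyruvate decarboxylase",
       c(pyr_c = -1, acald_c = 1, co2_c = 1), subsystem = "pdc_bypass"),
    rx("ADH",     "alcohol dehydrogenase",
       c(acald_c = -1, nadh_c = -1, etoh_c = 1), subsystem = "fermentation"),
    rx("ALDD",    "acetaldehyde dehydrogenase (NADP)",
       c(acald_c = -1, ac_c = 1, nadph_c = 1), subsystem = "pdc_bypass"),
    rx("ALDD_NAD", "acetaldehyde dehydrogenase (NAD)",
       c(acald_c = -1, ac_c = 1, nadh_c = 1), subsystem = "pdc_bypass"),
    rx("ACS",     "acetyl-CoA synthetase",
       setNames(c(-1, -a, 1, a, a), c("ac_m", "atp_m", "accoa_m", "amp_m", "ppi_m")),
       subsystem = "pdc_bypass"),
    rx("PDH",     "pyruvate dehydrogenase",
       c(pyr_m = -1, accoa_m = 1, nadh_m = 1, co2_m = 1), subsystem = "tca"),
    rx("TCA",     "TCA cycle (lumped, substrate-level phosphorylation)",
       c(accoa_m = -1, adp_m = -1, pi_m = -1, atp_m = 1, nadh_m = 3, co2_m = 2),
       subsystem = "tca"),
    rx("GLYOX",   "glyoxylate shunt (lumped)",
       c(accoa_m = -2, nadh_m = 3, co2_m = 4), subsystem = "glyoxylate"),
    rx("HMGCOAR", "HMG-CoA reductase (mevalonate pathway)",
       c(accoa_m = -3, nadph_c = -2, mva_c = 1), subsystem = "mva"),
    rx("ATPS",    "ATP synthase",
       c(adp_m = -1, pi_m = -1, nadh_m = -1, atp_m = 1), subsystem = "oxphos"),
    rx("NOX_m",   "uncoupled NADH oxidase",
       c(nadh_m = -1), subsystem = "oxphos"),
    rx("PPA_m",   "mitochondrial diphosphatase",
       c(ppi_m = -1, pi_m = 2), subsystem = "phosphate"),
    rx("ADK_m",   "adenylate kinase",
       c(amp_m = -1, atp_m = -1, adp_m = 2), subsystem = "phosphate"),
    rx("ATPM",    "ATP maintenance",
       c(atp_c = -1, adp_c = 1, pi_c = 1), subsystem = "maintenance"),
    rx("NADPHX",  "NADPH/NADH redox valve",
       c(nadph_c = -1, nadh_c = 1), subsystem = "redox"),
    rx("BIOMASS", "biomass (phosphate-retaining)",
       c(pyr_c = -1, atp_c = -8, nadph_c = -0.5, accoa_m = -0.2, atp_m = -0.3,
         adp_c = 8, adp_m = 0.3),
       subsystem = "biomass")
  )

  model <- stoich_model(
    metabolites = mets, reactions = rxns,
    compartments = c(e = "extracellular", c = "cytosol", m = "mitochondria"),
    objective = "BIOMASS", id = "toy_central_carbon"
  )
  if (!spec$include_pdc_bypass) {
    for (id in c("PDC", "ALDD", "ALDD_NAD", "ACt_cm", "ACS")) {
      model <- set_bounds(model, id, 0, 0)
    }
  }
  if (!spec$include_glyoxylate) model <- set_bounds(model, "GLYOX", 0, 0)
  if (!spec$include_mva_sink) {
    for (id in c("HMGCOAR", "MVAt", "EX_mva")) model <- set_bounds(model, id, 0, 0)
  }
  model
}

#' Parameters for random small-model generation
#'
#' Random models are the oracle-testing fixtures: small enough for
#' [brute_force_oracle()] (at most 12 reactions), always with finite bounds
#' (so the LP is bounded by construction) and with the zero flux vector
#' feasible (lower bounds never exceed zero), so a finite optimum always
#' exists.
#'
#' @param n_metabolites Number of metabolites (<= 10).
#' @param n_reactions Number of reactions (<= 12), including one uptake and
#'   one secretion exchange.
#' @param bound_magnitude Range the flux-bound magnitudes are drawn from.
#' @param reversibility_prob Probability that an internal reaction is
#'   reversible (negative lower bound).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `random_model_spec`.
#' @export
random_model_spec <- function(n_metabolites = 5, n_reactions = 8,
                              bound_magnitude = c(1, 10),
                              reversibility_prob = 0.3, seed = 1L) {
  if (n_metabolites > 10 || n_reactions > 12) {
    abort("random models are capped at 10 metabolites and 12 reactions")
  }
  stopifnot(n_metabolites >= 2, n_reactions >= 3)
  structure(
    list(n_metabolites = as.integer(n_metabolites),
         n_reactions = as.integer(n_reactions),
         bound_magnitude = bound_magnitude,
         reversibility_prob = reversibility_prob,
         seed = as.integer(seed)),
    class = "random_model_spec"
  )
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a seeded random small model
#'
#' @param spec A [random_model_spec()].
#' @return A [stoich_model()] with an uptake exchange on the first metabolite,
#'   a secretion exchange on the last (the objective), and random sparse
#'   internal reactions connecting every metabolite.
#' @export
generate_random_model <- function(spec = random_model_spec()) {
  stopifnot(inherits(spec, "random_model_spec"))
  M <- spec$n_metabolites; N <- spec$n_reactions
  with_local_seed(spec$seed, {
    mets <- tibble(id = sprintf("m%02d", seq_len(M)), compartment = "c")
    rmag <- function(k) runif(k, spec$bound_magnitude[1], spec$bound_magnitude[2])

    st_list <- vector("list", N - 2L)
    for (j in seq_len(N - 2L)) {
      ns <- sample(1:2, 1); np <- sample(1:2, 1)
      subs <- sample(M, ns)
      prods <- sample(setdiff(seq_len(M), subs), min(np, M - ns))
      st <- c(setNames(-sample(1:2, ns, replace = TRUE), mets$id[subs]),
              setNames(sample(1:2, length(prods), replace = TRUE), mets$id[prods]))
      st_list[[j]] <- st
    }
    # connect orphan metabolites so every model passes validation cleanly
    used <- unique(c("m01", mets$id[M], unlist(lapply(st_list, names))))
    for (o in setdiff(mets$id, used)) {
      j <- sample(length(st_list), 1)
      st_list[[j]] <- c(st_list[[j]], setNames(1, o))
    }
    ub <- rmag(N - 2L)
    lb <- ifelse(runif(N - 2L) < spec$reversibility_prob, -rmag(N - 2L), 0)
    internal <- tibble(
      id = sprintf("r%02d", seq_len(N - 2L)),
      stoichiometry = st_list, lower_bound = lb, upper_bound = ub
    )
    rxns <- bind_rows(
      tibble(id = "EX_in", stoichiometry = list(setNames(-1, "m01")),
             lower_bound = -rmag(1), upper_bound = 0),
      internal,
      tibble(id = "EX_out", stoichiometry = list(setNames(-1, mets$id[M])),
             lower_bound = 0, upper_bound = rmag(1))
    )
    stoich_model(metabolites = mets, reactions = rxns, objective = "EX_out",
                 id = sprintf("random_seed_%d", spec$seed))
  })
}

#' Brute-force LP oracle by vertex enumeration
#'
#' Independently computes the FBA optimum of a small model by enumerating the
#' basic feasible solutions (vertices) of the polytope
#' `{v : S v = 0, lb <= v <= ub}`: every choice of rank(S) basic columns with
#' the remaining variables fixed at a bound is solved and checked for
#' feasibility, and the maximal objective value over feasible vertices is
#' returned. Because all bounds are finite the polytope is bounded and, when
#' nonempty, attains its optimum at a vertex. This is a deliberately
#' exhaustive cross-check for [solve_fba()], refused above 12 reactions.
#'
#' @param model A [stoich_model()] with at most 12 reactions.
#' @param tol Feasibility tolerance for vertex acceptance.
#' @return The maximal objective value, or `NA_real_` if no feasible vertex
#'   exists (infeasible constraint set).
#' @export
brute_force_oracle <- function(model, tol = 1e-8) {
  n <- nrow(model$reactions)
  if (n > 12) {
    abort("brute_force_oracle refuses models with more than 12 reactions")
  }
  S <- as.matrix(stoichiometric_matrix(model))
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (any(lb > ub)) return(NA_real_)
  obj <- as.numeric(model$reactions$id == model$objective)
  r <- qr(S)$rank
  best <- NA_real_
  consider <- function(v) {
    if (all(v >= lb - tol) && all(v <= ub + tol) &&
        max(abs(S %*% v)) <= tol * max(1, max(abs(S)))) {
      val <- sum(obj * v)
      if (is.na(best) || val > best) best <<- val
    }
  }
  if (r == 0L) {
    # no equality coupling: optimum at a bound of the objective variable
    v <- ifelse(obj > 0, ub, lb)
    consider(v)
    consider(lb)
    return(best)
  }
  basis_sets <- utils::combn(n, r, simplify = FALSE)
  nonb_n <- n - r
  assignments <- if (nonb_n > 0) {
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), nonb_n)))
  } else {
    matrix(FALSE, 1, 0)
  }
  for (B in basis_sets) {
    SB <- S[, B, drop = FALSE]
    qb <- qr(SB)
    if (qb$rank < r) next
    Nset <- setdiff(seq_len(n), B)
    for (k in seq_len(nrow(assignments))) {
      vN <- ifelse(assignments[k, ], ub[Nset], lb[Nset])
      rhs <- if (length(Nset)) -S[, Nset, drop = FALSE] %*% vN else rep(0, nrow(S))
      vB <- tryCatch(qr.coef(qb, rhs), error = function(e) NULL)
      if (is.null(vB) || anyNA(vB)) next
      v <- numeric(n)
      v[B] <- vB
      if (length(Nset)) v[Nset] <- vN
      consider(v)
    }
  }
  best
}
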