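#' Cofactor production/consumption ledger
#'
#' Accounts for every reaction producing or consuming one metabolite in one
#' compartment under a solved flux distribution. The realized rate of
#' reaction r for metabolite m is `coeff(m, r) * v_r`: positive entries are
#' producers, negative are consumers, regardless of the reaction's declared
#' direction (the ledger reports realized roles). Entries below the reporting
#' tolerance are suppressed, and percentage shares are computed per side.
#' For a metabolite untouched by exchange reactions, total production equals
#' total consumption at steady state.
#'
#' @param model The [stoich_model()] that produced `dist`.
#' @param dist An optimal `flux_distribution`, normalized per 100 glucose for
#'   reporting on the conventional scale (shares are scale-invariant).
#' @param metabolite Metabolite id (compartment-specific, e.g. `"pi_m"`).
#' @param tol Reporting tolerance: entries with `|coeff * v| <= tol` are
#'   suppressed as LP noise.
#' @return A tibble of class `cofactor_ledger` with columns `side`
#'   (`"producer"`/`"consumer"`), `reaction`, `rate` (positive magnitudes)
#'   and `share` (percent within side). Attributes `metabolite`,
#'   `compartment`, `total_production`, `total_consumption`.
#' @export
#' @examples
#' toy <- generate_toy_model(toy_model_spec())
#' res <- run_scenario(toy, toy_scenarios(toy)$mutant_transcriptomic)
#' cofactor_ledger(toy, res$dist, "pi_m")
cofactor_ledger <- function(model, dist, metabolite, tol = 1e-6) {
  stopifnot(inherits(dist, "flux_distribution"))
  if (dist$status != "optimal") abort("ledger undefined for a non-optimal distribution")
  i <- met_row(model, metabolite)
  comp <- model$metabolites$compartment[i]
  rates <- vapply(seq_len(nrow(model$reactions)), function(j) {
    st <- model$reactions$stoichiometry[[j]]
    co <- unname(st[metabolite])
    if (is.na(co)) co <- 0
    co * dist$fluxes[[model$reactions$id[j]]]
  }, 0)
  keep <- abs(rates) > tol
  out <- tibble(
    side = ifelse(rates[keep] > 0, "producer", "consumer"),
    reaction = model$reactions$id[keep],
    rate = abs(rates[keep])
  )
  out <- out |>
    group_by(.data$side) |>
    mutate(share = 100 * .data$rate / sum(.data$rate)) |>
    ungroup() |>
    arrange(.data$side, desc(.data$rate))
  structure(out,
            class = c("cofactor_ledger", class(out)),
            metabolite = metabolite, compartment = comp,
            total_production = sum(rates[rates > tol]),
            total_consumption = -sum(rates[rates < -tol]))
}

#' @rdname cofactor_ledger
#' @param x A `cofactor_ledger`.
#' @param ... Unused.
#' @method glance cofactor_ledger
#' @export
glance.cofactor_ledger <- function(x, ...) {
  tibble(metabolite = attr(x, "metabolite"),
         compartment = attr(x, "compartment"),
         total_production = attr(x, "total_production"),
         total_consumption = attr(x, "total_consumption"),
         n_producers = sum(x$side == "producer"),
         n_consumers = sum(x$side == "consumer"))
}

#' Write a cofactor ledger to TSV
#'
#' Emits a comment header (metabolite, compartment, totals) followed by the
#' ledger columns in stable order, mirroring the structure of published
#' production/consumption tables.
#'
#' @param ledger A [cofactor_ledger()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ledger_tsv <- function(ledger, path) {
  hdr <- c(sprintf("# metabolite\t%s", attr(ledger, "metabolite")),
           sprintf("# compartment\t%s", attr(ledger, "compartment")),
           sprintf("# total_production\t%.12g", attr(ledger, "total_production")),
           sprintf("# total_consumption\t%.12g", attr(ledger, "total_consumption")),
           "side\treaction\trate\tshare")
  writeLines(hdr, path)
  if (nrow(ledger)) {
    write(sprintf("%s\t%s\t%.12g\t%.12g", ledger$side, ledger$reaction,
                  ledger$rate, ledger$share),
          file = path, append = TRUE)
  }
  invisible(path)
}

#' Compare two flux distributions reaction by reaction
#'
#' Joins two normalized distributions on their common reactions (with a
#' warning if the reaction sets differ), excludes reactions below the flux
#' tolerance in both, and classifies each remaining reaction by the ratio of
#' flux magnitudes `|b| / |a|`: `"up"` at or above `ratio_threshold`,
#' `"down"` at or below its reciprocal, `"unchanged"` otherwise. The signed
#' ratio `flux_b / flux_a` is reported where `|flux_a|` exceeds the
#' tolerance (infinite for fluxes appearing only in `b`), and a `sign_flip`
#' flag marks reactions whose direction reversed. Optional pathway
#' aggregates (named reaction sets) are summarised as total absolute flux in
#' each distribution with the percent change.
#'
#' @param a,b Normalized `flux_distribution` objects (scenario A and B).
#' @param ratio_threshold Magnitude-ratio threshold for the up/down lists.
#' @param flux_tol Fluxes at or below this magnitude in both scenarios are
#'   excluded.
#' @param aggregates Named list of reaction-id vectors (pathway sets), e.g.
#'   [toy_pathway_sets()].
#' @return A tibble of class `scenario_comparison` with columns `reaction`,
#'   `flux_a`, `flux_b`, `difference`, `ratio`, `sign_flip`, `class`;
#'   attribute `aggregates` holds the aggregate summary tibble.
#' @export
compare_scenarios <- function(a, b, ratio_threshold = 1.1, flux_tol = 1e-6,
                              aggregates = NULL) {
  stopifnot(inherits(a, "flux_distribution"), inherits(b, "flux_distribution"))
  for (d in list(a, b)) {
    if (d$basis != "per_100_glucose") {
      abort("both distributions must be normalized per 100 glucose units")
    }
  }
  common <- intersect(names(a$fluxes), names(b$fluxes))
  if (length(common) < length(a$fluxes) || length(common) < length(b$fluxes)) {
    warn("reaction sets differ; comparison restricted to their intersection")
  }
  fa <- a$fluxes[common]; fb <- b$fluxes[common]
  keep <- abs(fa) > flux_tol | abs(fb) > flux_tol
  fa <- fa[keep]; fb <- fb[keep]
  mag_ratio <- abs(fb) / pmax(abs(fa), .Machine$double.eps)
  mag_ratio[abs(fa) <= flux_tol] <- Inf
  cls <- ifelse(mag_ratio >= ratio_threshold, "up",
                ifelse(mag_ratio <= 1 / ratio_threshold, "down", "unchanged"))
  out <- tibble(
    reaction = names(fa),
    flux_a = unname(fa), flux_b = unname(fb),
    difference = unname(fb - fa),
    ratio = ifelse(abs(fa) > flux_tol, fb / fa, Inf * sign(fb)),
    sign_flip = abs(fa) > flux_tol & abs(fb) > flux_tol & sign(fa) != sign(fb),
    class = cls
  ) |> arrange(desc(abs(.data$difference)))
  agg <- NULL
  if (!is.null(aggregates)) {
    agg <- bind_rows(imap(aggregates, function(rxns, nm) {
      ids <- intersect(rxns, names(a$fluxes))
      ids_b <- intersect(rxns, names(b$fluxes))
      ta <- sum(abs(a$fluxes[ids])); tb <- sum(abs(b$fluxes[ids_b]))
      tibble(aggregate = nm, flux_a = ta, flux_b = tb,
             percent_change = if (ta > flux_tol) 100 * (tb - ta) / ta else NA_real_)
    }))
  }
  structure(out, class = c("scenario_comparison", class(out)),
            ratio_threshold = ratio_threshold, aggregates = agg)
}

#' Up/down reaction lists of a comparison
#'
#' @param comparison A [compare_scenarios()] result.
#' @return A list with character vectors `up` and `down`.
#' @export
comparison_lists <- function(comparison) {
  list(up = comparison$reaction[comparison$class == "up"],
       down = comparison$reaction[comparison$class == "down"])
}

#' Pathway aggregate summary of a comparison
#'
#' @param comparison A [compare_scenarios()] result built with `aggregates`.
#' @return The aggregate summary tibble, or `NULL`.
#' @export
comparison_aggregates <- function(comparison) {
  attr(comparison, "aggregates")
}

#' Packaged pathway reaction sets for the toy model
#'
#' Pathway aggregates (pentose phosphate pathway, glycolysis, PDC bypass,
#' TCA, glyoxylate shunt, mevalonate sink, fermentation) as an editable YAML
#' file, since subsystem annotations differ between model versions.
#'
#' @return Named list of reaction-id vectors.
#' @export
toy_pathway_sets <- function() {
  doc <- yaml::read_yaml(system.file("extdata", "toy_pathway_sets.yaml",
                                     package = "isoflux"))
  lapply(doc, unlist)
}

#' Branch-point consumption shares
#'
#' Splits the total consumption flux of a branch-point metabolite among a
#' set of listed branch reactions, reporting each share as a percentage of
#' total consumption; consumption not attributed to a listed reaction is
#' reported as `"other"`. Shares including `"other"` sum to 100.
#'
#' @param model The [stoich_model()].
#' @param dist An optimal `flux_distribution`.
#' @param branch_point Metabolite id (e.g. cytosolic pyruvate).
#' @param branch_reactions Reaction ids consuming the branch point.
#' @param tol Flux tolerance.
#' @return A tibble with columns `reaction`, `flux` and `share` (percent),
#'   ending with the `"other"` row.
#' @export
#' @examples
#' toy <- generate_toy_model(toy_model_spec())
#' res <- run_scenario(toy, toy_scenarios(toy)$control)
#' pathway_summary(toy, res$dist, "pyr_c", c("PDC", "PYRt_cm"))
pathway_summary <- function(model, dist, branch_point, branch_reactions,
                            tol = 1e-9) {
  ledger <- cofactor_ledger(model, dist, branch_point, tol = tol)
  cons <- ledger[ledger$side == "consumer", ]
  total <- attr(ledger, "total_consumption")
  if (total <= tol) {
    abort(sprintf("branch point '%s' has zero consumption flux", branch_point))
  }
  bad <- setdiff(branch_reactions, model$reactions$id)
  if (length(bad)) {
    abort(sprintf("unknown branch reaction(s): %s", paste(bad, collapse = ", ")))
  }
  flux <- vapply(branch_reactions, function(id) {
    k <- match(id, cons$reaction)
    if (is.na(k)) 0 else cons$rate[k]
  }, 0)
  vals <- c(unname(flux), total - sum(flux))
  tibble(reaction = c(branch_reactions, "other"),
         flux = vals,
         share = 100 * vals / total)
}
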