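scenario_results <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      toy <- toy_model_default()
      cache <<- run_scenarios(toy, toy_scenarios_cached(toy))
    }
    cache
  }
})

test_that("ledgers balance production and consumption for internal metabolites", {
  toy <- toy_model_default()
  res <- scenario_results()
  internal <- internal_metabolites(toy)
  for (r in res$result) {
    if (r$status != "optimal") next
    for (met in c("atp_c", "atp_m", "pi_m", "nadh_c", "nadph_c", "accoa_m")) {
      led <- cofactor_ledger(toy, r$dist, met)
      g <- glance(led)
      if (met %in% internal) {
        expect_equal(g$total_production, g$total_consumption, tolerance = 1e-6)
      }
      for (side in unique(led$side)) {
        expect_equal(sum(led$share[led$side == side]), 100, tolerance = 0.1)
      }
      expect_true(all(led$rate > 1e-6))
    }
  }
})

test_that("ledger shares are scale invariant", {
  toy <- toy_model_default()
  raw <- solve_fba(toy, parsimonious = TRUE, glucose_exchange = "EX_glc")
  nrm <- normalize_fluxes(raw)
  l_raw <- cofactor_ledger(toy, raw, "atp_c")
  l_nrm <- cofactor_ledger(toy, nrm, "atp_c")
  expect_equal(l_nrm$share, l_raw$share, tolerance = 1e-9)
  expect_equal(l_nrm$reaction, l_raw$reaction)
})

test_that("ledger assigns sides by realized flux and flags exchanges", {
  toy <- toy_model_default()
  dist <- scenario_results()$result[[1]]$dist
  led <- cofactor_ledger(toy, dist, "glc_e")
  # glucose uptake: the exchange runs negative, so it produces extracellular
  # glucose for the transporter to consume
  expect_equal(led$reaction[led$side == "producer"], "EX_glc")
  expect_equal(led$reaction[led$side == "consumer"], "GLCt")

  expect_error(cofactor_ledger(toy, dist, "unobtainium"), "unobtainium")
})

test_that("mitochondrial phosphate is supplied by diphosphatase plus transport", {
  toy <- toy_model_default()
  res <- scenario_results()
  dist <- res$result[[3]]$dist  # mutant + transcriptomic constraints
  led <- cofactor_ledger(toy, dist, "pi_m")
  prod <- led[led$side == "producer", ]
  expect_setequal(prod$reaction, c("PPA_m", "PIt_cm"))
  # the diphosphatase dominates, the cytosolic transporter tops up
  expect_gt(prod$share[prod$reaction == "PPA_m"], 50)
  expect_lt(prod$share[prod$reaction == "PIt_cm"], 50)
})

test_that("comparing a distribution with itself yields empty up/down lists", {
  d <- scenario_results()$result[[1]]$dist
  cmp <- compare_scenarios(d, d)
  lists <- comparison_lists(cmp)
  expect_length(lists$up, 0)
  expect_length(lists$down, 0)
  expect_true(all(cmp$class == "unchanged"))
})

test_that("a directive-forced doubling lands the reaction in the up list", {
  toy <- toy_model_default()
  base <- scenario_spec("base", measured_rates("b", -10, 12, 0.5, 1, 0.24),
                        directives = {
                          d <- constraint_directive("HMGCOAR", "upper_bound", 0.48)
                          d$resolvable <- TRUE
                          d
                        })
  doubled <- scenario_spec("doubled", base$rates, directives = dplyr::bind_rows(
    base$directives,
    {
      d <- constraint_directive("PYRt_cm", "lower_bound", 30)
      d$resolvable <- TRUE
      d
    }))
  ra <- run_scenario(toy, base)
  rb <- run_scenario(toy, doubled)
  cmp <- compare_scenarios(ra$dist, rb$dist,
                           aggregates = toy_pathway_sets())
  expect_true("PYRt_cm" %in% comparison_lists(cmp)$up)
  # reactions land in at most one list
  expect_length(intersect(comparison_lists(cmp)$up,
                          comparison_lists(cmp)$down), 0)
  agg <- comparison_aggregates(cmp)
  expect_true(all(c("ppp", "mva", "tca") %in% agg$aggregate))
})

test_that("comparison warns on mismatched reaction sets and restricts to intersection", {
  d <- scenario_results()$result[[1]]$dist
  d2 <- d
  d2$fluxes <- d2$fluxes[-1]
  expect_warning(cmp <- compare_scenarios(d, d2), "intersection")
  expect_false(names(d$fluxes)[1] %in% cmp$reaction)
})

test_that("mutant scenarios show the expected pathway shifts on the toy model", {
  res <- scenario_results()
  cmp <- compare_scenarios(res$result[[1]]$dist, res$result[[3]]$dist,
                           aggregates = toy_pathway_sets())
  agg <- comparison_aggregates(cmp)
  # the mevalonate sink carries more flux under the mutant constraints,
  # fermentation less (ethanol secretion is 11% lower)
  expect_gt(agg$flux_b[agg$aggregate == "mva"],
            agg$flux_a[agg$aggregate == "mva"])
  expect_lt(agg$flux_b[agg$aggregate == "fermentation"],
            agg$flux_a[agg$aggregate == "fermentation"])
})

test_that("branch-point shares split consumption and sum to 100 with 'other'", {
  toy <- toy_model_default()
  res <- scenario_results()
  ctrl <- res$result[[1]]$dist

  ps <- pathway_summary(toy, ctrl, "pyr_c", c("PDC", "PYRt_cm", "BIOMASS"))
  expect_equal(sum(ps$share), 100, tolerance = 0.1)
  expect_equal(ps$reaction[length(ps$reaction)], "other")
  # the decarboxylase is the dominant pyruvate consumer in the control
  expect_gt(ps$share[ps$reaction == "PDC"], 50)

  # single-consumer branch point gets 100%
  ps2 <- pathway_summary(toy, ctrl, "acald_c", c("ADH", "ALDD", "ALDD_NAD"))
  expect_equal(sum(ps2$share[ps2$reaction != "other"]), 100, tolerance = 0.1)

  # zero-consumption branch point errors
  idle <- solve_fba(set_bounds(chain_model(), "EX_A", 0, 0))
  expect_error(pathway_summary(chain_model(), idle, "B_c", "EX_B"),
               "zero consumption")

  expect_error(pathway_summary(toy, ctrl, "pyr_c", "GHOST"), "GHOST")
})

test_that("ledgers serialize to TSV with their header block", {
  toy <- toy_model_default()
  led <- cofactor_ledger(toy, scenario_results()$result[[3]]$dist, "pi_m")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_ledger_tsv(led, p)
  lines <- readLines(p)
  expect_true(any(grepl("^# metabolite\tpi_m", lines)))
  body <- utils::read.delim(p, comment.char = "#")
  expect_equal(nrow(body), nrow(led))
})
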