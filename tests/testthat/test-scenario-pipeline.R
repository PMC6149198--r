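test_that("measured rates enforce sign conventions and load from TSV", {
  expect_error(measured_rates("x", 10, 1, 1, 1, 0.2), "negative")
  expect_error(measured_rates("x", -10, 1, 1, 1, -0.2), "non-negative")

  tab <- read_rates_tsv(system.file("extdata", "toy_rates.tsv",
                                    package = "isoflux"))
  expect_equal(tab$strain, c("control", "mutant"))
  r <- as_measured_rates(tab[2, ])
  expect_s3_class(r, "measured_rates")
  expect_equal(r$glucose, -10)
  expect_equal(r$ethanol, 10.68)
})

test_that("exchange constraints fix the four measured exchanges and nothing else", {
  toy <- toy_model_default()
  rates <- measured_rates("control", -10, 15, 0.5, 1, 0.24)
  m <- apply_exchange_constraints(toy, rates)
  b <- reaction_bounds(m)
  expect_equal(unlist(b[b$id == "EX_glc", -1], use.names = FALSE), c(-10, -10))
  expect_equal(unlist(b[b$id == "EX_etoh", -1], use.names = FALSE), c(15, 15))
  expect_equal(unlist(b[b$id == "EX_ac", -1], use.names = FALSE), c(0.5, 0.5))
  # other exchanges untouched
  expect_equal(unlist(b[b$id == "EX_co2", -1], use.names = FALSE), c(0, 1000))

  expect_error(
    apply_exchange_constraints(toy, rates, exchange_map = c(
      glucose = "EX_glc", ethanol = "EX_etoh", acetate = "EX_ac")),
    "glycerol")

  # zero acetate secretion keeps the toy network feasible
  z <- apply_exchange_constraints(toy, measured_rates("z", -10, 12, 0, 1, 0.2))
  expect_equal(solve_fba(z)$status, "optimal")
})

test_that("predicted growth is validated against the measured rate", {
  toy <- toy_model_default()
  res <- run_scenario(toy, toy_scenarios_cached()$control)
  expect_equal(res$status, "optimal")
  expect_named(res$growth, c("strain", "predicted", "measured", "ratio"))
  expect_equal(res$growth$measured, 0.24)
  expect_equal(res$growth$predicted, res$dist$objective_value)
  expect_lt(abs(res$growth$ratio - 1), 0.1)  # toy calibration tracks measurement
})

test_that("transcriptomic fold changes translate into flux bounds by the stated rule", {
  # control distribution with known fluxes
  ctrl <- isoflux:::new_flux_distribution(
    c(PDC = 80, R_down = 40, R_neg = -30, R_zero = 0),
    objective_value = 1, status = "optimal", basis = "per_100_glucose",
    glucose_exchange = "EX_glc")

  d <- derive_transcriptomic_constraints(
    ctrl, tibble::tibble(reaction = "PDC", fold = 2, direction = "up"))
  expect_equal(d$kind, "lower_bound")
  expect_equal(d$value, 160)

  # identity fold: directive equals the control flux
  d1 <- derive_transcriptomic_constraints(
    ctrl, tibble::tibble(reaction = "PDC", fold = 1, direction = "up"))
  expect_equal(d1$value, 80)

  # down-regulation and negative control flux preserve direction
  d2 <- derive_transcriptomic_constraints(
    ctrl, tibble::tibble(reaction = c("R_down", "R_neg"),
                         fold = c(0.5, 2), direction = c("down", "up")))
  expect_equal(d2$kind, c("upper_bound", "upper_bound"))
  expect_equal(d2$value, c(20, -60))

  # zero control flux cannot be scaled
  expect_warning(
    dz <- derive_transcriptomic_constraints(
      ctrl, tibble::tibble(reaction = "R_zero", fold = 2, direction = "up")),
    "zero")
  expect_false(dz$resolvable)

  expect_error(
    derive_transcriptomic_constraints(
      ctrl, tibble::tibble(reaction = "GHOST", fold = 2, direction = "up")),
    "GHOST")
})

test_that("the isoprenoid target fix carries provenance and surfaces infeasibility", {
  toy <- toy_model_default()
  base <- toy_scenarios_cached()$mutant
  base$directives <- base$directives[base$directives$source != "target_fix", ]

  expect_no_warning(
    spec <- set_target_flux_from_fold_change(base, control_capacity = 0.48,
                                             fold = 2.25, chosen_value = 1.5))
  expect_equal(spec$target_provenance,
               list(control_capacity = 0.48, fold = 2.25, chosen_value = 1.5))
  fix <- spec$directives[spec$directives$source == "target_fix", ]
  expect_equal(fix$kind, "fix")
  expect_equal(fix$value, 1.5)
  expect_equal(run_scenario(toy, spec)$status, "optimal")

  # chosen value of zero blocks the sink but stays feasible
  z <- set_target_flux_from_fold_change(base, 0.48, 2.25, 0)
  rz <- run_scenario(toy, z)
  expect_equal(rz$status, "optimal")
  expect_equal(rz$isoprenoid_flux, 0, tolerance = 1e-9)

  # chosen value above attainable capacity: warned, then infeasible at solve
  cap <- run_scenario(toy, base)$isoprenoid_capacity
  expect_warning(
    big <- set_target_flux_from_fold_change(base, 0.48, 2.25, cap + 100,
                                            scenario_capacity = cap),
    "exceed")
  expect_equal(run_scenario(toy, big)$status, "infeasible")

  expect_error(set_target_flux_from_fold_change(base, 0.48, -1, 1.5),
               "positive")
})

test_that("the five packaged scenarios run with the designed statuses", {
  toy <- toy_model_default()
  specs <- toy_scenarios_cached()
  expect_named(specs, c("control", "mutant", "mutant_transcriptomic",
                        "mutant_high_phosphate", "mutant_pdh_test"))
  res <- run_scenarios(toy, specs)
  expect_equal(res$status, c("optimal", "optimal", "optimal", "optimal",
                             "infeasible"))

  # every optimal scenario reports |glucose| = 100 after normalization
  for (r in res$result) {
    if (r$status != "optimal") next
    expect_equal(abs(r$dist$fluxes[[r$dist$glucose_exchange]]), 100,
                 tolerance = 1e-9)
    expect_equal(r$dist$basis, "per_100_glucose")
  }

  # the PDH test is diagnosed: dropping the forced-PDH directive restores
  # feasibility
  pdh <- res$result[[5]]
  rep <- pdh$constraint_report
  expect_true(rep$binding[rep$source == "pdh_test"])

  # mutant scenarios route strictly more flux into the mevalonate sink
  expect_gt(res$result[[2]]$isoprenoid_flux, res$result[[1]]$isoprenoid_flux)
})

test_that("empty directive lists reduce to plain FBA on measured rates", {
  toy <- toy_model_default()
  spec <- scenario_spec("plain", measured_rates("control", -10, 12, 0.5, 1, 0.24),
                        tala_lower_bound = NULL)
  res <- run_scenario(toy, spec)
  direct <- solve_fba(apply_exchange_constraints(toy, spec$rates),
                      parsimonious = TRUE, glucose_exchange = "EX_glc")
  expect_equal(res$status, "optimal")
  expect_equal(res$dist$objective_value, direct$objective_value,
               tolerance = 1e-9)
})

test_that("directives are idempotent and nested directives never raise the optimum", {
  toy <- toy_model_default()
  specA <- toy_scenarios_cached()$mutant
  resA <- run_scenario(toy, specA)

  # re-applying the same directives changes nothing
  specAA <- specA
  specAA$directives <- dplyr::bind_rows(specA$directives, specA$directives)
  resAA <- run_scenario(toy, specAA)
  expect_equal(resAA$dist$fluxes, resA$dist$fluxes, tolerance = 1e-9)

  # superset of directives: objective can only drop
  specB <- specA
  extra <- constraint_directive("PYRt_cm", "upper_bound", 5, source = "extra")
  extra$resolvable <- TRUE
  specB$directives <- dplyr::bind_rows(specA$directives, extra)
  resB <- run_scenario(toy, specB)
  expect_lte(resB$dist$objective_value, resA$dist$objective_value + 1e-9)
})

test_that("scenario YAML files round-trip through the reader", {
  p <- system.file("extdata", "scenarios", "toy_mutant.yaml",
                   package = "isoflux")
  spec <- read_scenario_yaml(p)
  expect_s3_class(spec, "scenario_spec")
  expect_equal(spec$name, "mutant")
  expect_equal(spec$tala_lower_bound, 11)
  expect_equal(spec$rates$glucose, -10)
  expect_true("target_fix" %in% spec$directives$source)
})
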