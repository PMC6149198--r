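test_that("JSON round trip preserves ids, stoichiometry and bounds", {
  m <- toy_model_default()
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, p1)
  m2 <- read_model(p1, format = "bigg_json")
  write_model_json(m2, p2)
  m3 <- read_model(p2)

  expect_equal(m2$reactions$id, m$reactions$id)
  expect_equal(m2$metabolites$id, m$metabolites$id)
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
  for (j in seq_len(nrow(m$reactions))) {
    a <- m$reactions$stoichiometry[[j]]
    b <- m2$reactions$stoichiometry[[j]]
    expect_equal(b[names(a)], a)
  }
  expect_identical(readLines(p1), readLines(p2))  # byte-identical re-serialization
})

test_that("a 3-reaction chain model file is read back faithfully", {
  p <- withr::local_tempfile(fileext = ".json")
  write_model_json(chain_model(), p)
  m <- read_model(p)
  expect_equal(nrow(m$metabolites), 2L)
  expect_equal(nrow(m$reactions), 3L)
  expect_equal(m$objective, "EX_B")
  expect_true(all(m$reactions$is_exchange == c(TRUE, FALSE, TRUE)))
})

test_that("SBML L3/FBC reading matches the equivalent JSON model", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(minimal_sbml_text(), p)
  m <- read_model(p)   # format auto-detected from extension
  expect_equal(nrow(m$metabolites), 3L)
  expect_equal(nrow(m$reactions), 4L)
  expect_equal(m$objective, "EX_B")
  expect_equal(reaction_bounds(m)$lower_bound, c(-10, 0, 0, 0))
  expect_equal(m$metabolites$formula[m$metabolites$id == "A_c"], "C6H12O6")
  expect_equal(solve_fba(m)$objective_value, 10)
})

test_that("malformed files and dangling references are rejected with names", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", p)
  expect_error(read_model(p), "cannot parse")

  # reaction referencing an undeclared metabolite
  doc <- jsonlite::fromJSON(
    '{"id":"bad","metabolites":[{"id":"A_c","compartment":"c"}],
      "reactions":[{"id":"R1","metabolites":{"A_c":-1,"GHOST":1},
                    "lower_bound":0,"upper_bound":10,
                    "objective_coefficient":1}]}',
    simplifyVector = FALSE)
  p2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, p2, auto_unbox = TRUE)
  expect_error(read_model(p2), "GHOST")
})

test_that("validate_model reports each invariant violation as a diagnostic", {
  m <- toy_model_default()
  expect_equal(nrow(validate_model(m)), 0L)

  bad <- set_bounds(m, "PDC", 5, 1)
  d <- validate_model(bad)
  expect_true(any(d$code == "inverted_bounds" & d$id == "PDC"))

  orphan <- m
  orphan$metabolites <- dplyr::bind_rows(
    orphan$metabolites,
    tibble::tibble(id = "lonely_c", name = "lonely", compartment = "c",
                   formula = NA_character_, charge = NA_integer_))
  d2 <- validate_model(orphan)
  expect_true(any(d2$code == "orphan_metabolite" & d2$id == "lonely_c"))
  expect_true(all(d2$level[d2$code == "orphan_metabolite"] == "warning"))

  ghost_cp <- m
  ghost_cp$metabolites$compartment[1] <- "x"
  expect_true(any(validate_model(ghost_cp)$code == "unknown_compartment"))
})

test_that("stoichiometric matrix has documented entries, orders and dims", {
  m <- chain_model()
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(2L, 3L))
  expect_equal(rownames(S), m$metabolites$id)
  expect_equal(colnames(S), m$reactions$id)
  expect_equal(S["A_c", "R_AB"], -1)
  expect_equal(S["B_c", "R_AB"], 1)
  expect_equal(sum(S[, "EX_A"] != 0), 1)  # exchange column: single entry

  toy <- toy_model_default()
  expect_equal(dim(stoichiometric_matrix(toy)),
               c(nrow(toy$metabolites), nrow(toy$reactions)))
})

test_that("curation applies reversibility, deactivation and additions in order", {
  m <- toy_model_default()

  # identity: empty recipe changes nothing
  expect_equal(apply_curation(m, curation_recipe()), m)

  # deactivation blocks the reaction and can only lower the optimum
  z0 <- solve_fba(m)$objective_value
  cur <- apply_curation(m, curation_recipe(deactivate = "TCA"))
  expect_equal(unlist(reaction_bounds(cur)[cur$reactions$id == "TCA", -1],
                      use.names = FALSE), c(0, 0))
  expect_lte(solve_fba(cur)$objective_value, z0 + 1e-9)

  # addition increases the reaction count by exactly one
  add <- tibble::tibble(id = "PIt_mc_added",
                        stoichiometry = list(c(pi_m = -1, pi_c = 1)),
                        lower_bound = 0, upper_bound = 1000)
  cur2 <- apply_curation(m, curation_recipe(add_transport = add))
  expect_equal(nrow(cur2$reactions), nrow(m$reactions) + 1L)

  # determinism: same recipe, byte-identical serialization
  rec <- curation_recipe(
    reversibility = tibble::tibble(id = "PIt_cm", lower_bound = -1000,
                                   upper_bound = 1000),
    deactivate = "GLYOX", add_transport = add)
  pa <- withr::local_tempfile(fileext = ".json")
  pb <- withr::local_tempfile(fileext = ".json")
  write_model_json(apply_curation(m, rec), pa)
  write_model_json(apply_curation(m, rec), pb)
  expect_identical(readLines(pa), readLines(pb))

  # errors name the offending ids
  expect_error(apply_curation(m, curation_recipe(deactivate = "NOPE")), "NOPE")
  dup <- tibble::tibble(id = "PDC", stoichiometry = list(c(pyr_c = -1)),
                        lower_bound = 0, upper_bound = 1)
  expect_error(apply_curation(m, curation_recipe(add_transport = dup)), "PDC")
})

test_that("curation recipes load from YAML", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "reversibility:",
    "  - {id: PIt_cm, lower_bound: -1000, upper_bound: 1000}",
    "deactivate: [GLYOX]",
    "add_transport:",
    "  - id: PIt_mc_added",
    "    metabolites: {pi_m: -1, pi_c: 1}",
    "    lower_bound: 0",
    "    upper_bound: 1000"), p)
  rec <- read_curation_recipe(p)
  m <- apply_curation(toy_model_default(), rec)
  expect_equal(m$reactions$lower_bound[m$reactions$id == "PIt_cm"], -1000)
  expect_equal(m$reactions$upper_bound[m$reactions$id == "GLYOX"], 0)
  expect_true("PIt_mc_added" %in% m$reactions$id)

  tmpl <- system.file("extdata", "genome_scale", "imm904_curation.yaml",
                      package = "isoflux")
  expect_s3_class(read_curation_recipe(tmpl), "curation_recipe")
})
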