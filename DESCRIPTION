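Package: isoflux
Title: Constraint-Based Flux Balance Scenarios for Isoprenoid-Overproducing Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stoichiometric flux balance analysis (FBA) with staged constraint
    scenarios for studying isoprenoid (mevalonate) pathway flux rerouting in
    Saccharomyces cerevisiae. Provides readers for SBML Level 3 (FBC) and
    BiGG-style JSON models, model curation (reversibility edits, reaction
    deactivation, transport additions), a biomass-maximizing linear-programming
    core with parsimonious refinement and flux-capacity maximization,
    normalization of fluxes to 100 glucose units, transcriptomic and
    transport/diffusion bound constraints derived from control-strain fluxes,
    per-compartment cofactor production/consumption ledgers (ATP, phosphate,
    NADH, NADPH), between-scenario flux comparison, and a compartmentalized
    synthetic central-carbon model plus a brute-force vertex-enumeration LP
    oracle for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
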