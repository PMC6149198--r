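# isoflux

Constraint-based flux balance scenarios for studying how *Saccharomyces
cerevisiae* reroutes central carbon metabolism towards the isoprenoid
(mevalonate) pathway — the analysis style used for phosphate-limited,
pyruvate-decarboxylase-driven overproducer strains.

## What it does

Flux balance analysis (FBA) finds a steady-state flux vector `v` maximizing
a biomass objective `c'v` subject to `S v = 0` and bounds `lb <= v <= ub`,
where `S` is the stoichiometric matrix. On top of that core, `isoflux`
implements the staged constraint procedure of a control-vs-mutant strain
comparison:

1. **Model handling** — read SBML Level 3 (FBC) or BiGG-style JSON models,
   validate them, and apply a curation recipe (reversibility edits,
   deactivations, transport additions).
2. **FBA engine** — biomass maximization with parsimonious refinement
   (minimal total flux at the fixed optimum, for a deterministic
   representative solution), reaction flux-capacity maximization,
   mass-balance checking, and normalization of all fluxes to 100 units of
   glucose uptake.
3. **Scenario pipeline** — measured uptake/secretion rates fix the glucose,
   ethanol, acetate and glycerol exchanges; a transaldolase (TALA) lower
   bound of 11 per 100 glucose pins PPP activity; transcriptomic fold
   changes become flux bounds relative to control-strain fluxes; diffusion
   caps restrict transport; the isoprenoid target (HMGCOAR) can be fixed.
   Infeasible scenarios are diagnosed directive by directive.
4. **Ledgers and comparisons** — per-compartment cofactor
   production/consumption ledgers (ATP, phosphate, NADH, NADPH) with
   percentage shares, branch-point partitioning, and between-scenario
   up/down reaction lists with pathway aggregates.
5. **Synthetic fixtures** — a three-compartment toy central-carbon model
   (glycolysis, PPP, the PDC bypass with its ATP cost, PDH, TCA, glyoxylate
   shunt, mevalonate sink, explicit ATP/Pi/NAD(P)H) whose qualitative
   behaviour is forced by construction, plus seeded random models and a
   brute-force vertex-enumeration LP oracle that independently verifies the
   solver.

Results are tibbles; fitted objects have `tidy()`/`glance()` methods and
`autoplot()` figures.

## Worked example

```r
library(isoflux)

toy <- generate_toy_model(toy_model_spec())
res <- run_scenarios(toy, toy_scenarios(toy))
res[, c("name", "status", "growth_predicted", "growth_measured", "isoprenoid_flux")]
#> # A tibble: 5 × 5
#>   name                  status     growth_predicted growth_measured isoprenoid_flux
#>   <chr>                 <chr>                 <dbl>           <dbl>           <dbl>
#> 1 control               optimal               0.241            0.24            0.48
#> 2 mutant                optimal               0.193            0.19            1.5
#> 3 mutant_transcriptomic optimal               0.193            0.19            1.5
#> 4 mutant_high_phosphate optimal               0.241            0.24            1.5
#> 5 mutant_pdh_test       infeasible           NA                0.19           NA
```

Predicted growth tracks the measured rates because the toy biomass reaction
retains phosphate, making growth phosphate-limited by construction: the
mutant scenarios run at a lower phosphate supply, and relieving it
(`mutant_high_phosphate`) restores control-level growth without raising the
fixed mevalonate flux. The PDH test — forcing pyruvate-dehydrogenase flux on
top of the transcriptomic constraints — is infeasible, and the report names
the culprit:

```r
res$result[[5]]$constraint_report
#>   reaction kind        value reference_flux source               resolvable binding
#> 1 PDC      lower_bound 150            125   transcriptomic       TRUE       FALSE
#> 2 PYRt_cm  upper_bound  10             NA   diffusion            TRUE       FALSE
#> 3 EX_pi    lower_bound -16             NA   phosphate_limitation TRUE       FALSE
#> 4 PDH      lower_bound  60             NA   pdh_test             TRUE       TRUE
#> 5 HMGCOAR  fix           1.5           NA   target_fix           TRUE       FALSE
```

The mitochondrial phosphate ledger under transcriptomic constraints shows
the diphosphatase-dominated supply with a cytosolic transport top-up:

```r
cofactor_ledger(toy, res$result[[3]]$dist, "pi_m")
#> # A tibble: 3 × 4
#>   side     reaction   rate  share
#>   <chr>    <chr>     <dbl>  <dbl>
#> 1 consumer ATPS     57.0   100
#> 2 producer PPA_m    56.4    98.99
#> 3 producer PIt_cm    0.578   1.01
```

All fluxes are per 100 units of glucose uptake. Genome-scale models run
through the same functions (`read_model()` on a BiGG JSON or SBML file,
`apply_curation()` with the recipe in `inst/extdata/genome_scale/`, then
`run_scenario()` with a scenario YAML); the shipped genome-scale files are
editable templates whose measured-rate and constraint-table entries must be
filled from the corresponding study supplement.

A thin command-line wrapper lives at `inst/scripts/isoflux.R`:

```sh
Rscript inst/scripts/isoflux.R make-toy --out toy.json
Rscript inst/scripts/isoflux.R run --model toy.json \
    --scenario inst/extdata/scenarios/toy_mutant.yaml --out out/
```

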