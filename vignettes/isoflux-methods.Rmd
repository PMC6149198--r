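---
title: "Constraint scenarios for isoprenoid flux rerouting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint scenarios for isoprenoid flux rerouting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoflux)
```

## The modelling problem

Flux balance analysis (FBA) treats a metabolic network as a stoichiometric
matrix $S$ (metabolites $\times$ reactions) and asks for a steady-state flux
vector $v$ maximizing a biomass objective $c^\top v$ subject to

$$ S v = 0, \qquad lb \le v \le ub. $$

`isoflux` implements this core together with the staged constraint procedure
used to study how a yeast strain reroutes central carbon metabolism towards
the isoprenoid (mevalonate, MVA) pathway: measured exchange rates pin the
boundary fluxes, a transaldolase lower bound pins pentose phosphate pathway
(PPP) activity, transcriptomic fold changes become flux bounds relative to
the control strain, transport/diffusion caps restrict intercompartment
fluxes, and the isoprenoid flux itself can be fixed to an experimentally
chosen target. Cofactor ledgers (ATP, phosphate, NADH, NADPH, per
compartment) and scenario comparisons then read the biology out of the
solved flux vectors.

## The linear-programming core

The solver is a bounded-variable two-phase primal simplex written for this
package (`R/lp.R`), used through `solve_fba()`, `maximize_reaction_flux()`
and the parsimonious refinement. Design points:

* **Finite bounds.** Model readers clamp infinite bounds to $\pm 1000$ (the
  BiGG convention), so every LP is bounded and "unbounded" never needs to be
  a solver outcome; infeasibility is a first-class status, reported through
  the result object rather than an exception, because one of the packaged
  scenarios is infeasible *by design*.
* **Degeneracy.** FBA LPs are heavily degenerate. Bland's smallest-index
  pivoting rule is used for entering and leaving variables, which guarantees
  termination at the cost of some speed — irrelevant at the problem sizes
  this package targets (tens to a few hundred variables).
* **Tolerances.** Feasibility tolerance $10^{-9}$; reporting tolerance
  $10^{-6}$ (ledger inclusion, mass-balance checks). Both reflect
  double-precision LP practice.
* **Alternate optima.** The studies this pipeline reproduces report a single
  flux value per reaction, which an optimal *value* does not determine. All
  reported per-reaction fluxes therefore use parsimonious refinement: among
  the biomass-optimal solutions, minimize $\sum_r |v_r|$ with the objective
  pinned at its optimum. The refinement is kept linear by splitting each
  flux into nonnegative forward and reverse parts. Exact per-reaction
  agreement with any published figure still depends on that publication's
  own (usually unstated) alternate-optima handling, so per-reaction numbers
  are treated as soft, qualitative checks.
* **Verification.** `brute_force_oracle()` independently maximizes small
  LPs by enumerating the basic feasible solutions (all choices of
  $\mathrm{rank}(S)$ basic columns, non-basic variables at either bound,
  feasibility-checked). It refuses models above 12 reactions; on the seeded
  random-model family the solver and oracle agree to $10^{-6}$
  (observed: $\sim 10^{-14}$).

## The scenario procedure

`run_scenario()` applies constraints in a fixed order mirroring the staged
narrative of the analysis it reimplements: measured rates → transaldolase
bound → transcriptomic directives → diffusion directives → isoprenoid target
fix. Two unit conventions meet here: measured rates are raw
(mmol gDCW$^{-1}$ h$^{-1}$), while all directive values and every reported
flux are per 100 units of glucose uptake, the field's reporting convention.
Directives are rescaled to raw units with the scenario's measured glucose
uptake before solving, and solved fluxes are rescaled back with
`normalize_fluxes()` (glucose magnitude exactly 100 in every optimal
result).

The transcriptomic rule formalizes "constraints calculated from
control-strain fluxes": an up-regulated reaction with fold $f$ and control
flux $v^{ctrl}$ receives a lower bound $f \, v^{ctrl}$ in the control flux
direction; a down-regulated one receives the corresponding upper bound. A
zero control flux cannot be scaled; such directives are flagged unresolvable
with a warning rather than silently dropped. Where a published supplement
provides explicit bound values, those values should be entered as plain
`lower_bound`/`upper_bound` directives and override the computed rule.

The isoprenoid target (`set_target_flux_from_fold_change()`) is an explicit
parameter, not an arithmetic consequence of the control capacity and the
experimental fold change: the study this follows computed a control
capacity of 0.48 and observed a 2.25-fold experimental increase, then chose
1.5 units per 100 glucose as the fixed mutant flux. The function records
capacity and fold as provenance and fixes the chosen value.

Infeasible scenarios return a constraint report in which each directive is
marked `binding` if removing it alone restores feasibility — the packaged
PDH test is diagnosed this way (the forced pyruvate dehydrogenase flux
cannot be supplied through the capped mitochondrial pyruvate transporter).

## The synthetic central-carbon model

The toy model (`generate_toy_model()`) is a 30-metabolite, 38-reaction,
three-compartment caricature of yeast central carbon metabolism built so
that every qualitative claim the scenario suite asserts is forced by
stoichiometric construction, not by tuning:

* **Phosphate-limited growth.** The biomass reaction consumes 8 ATP$_c$ +
  0.3 ATP$_m$ per unit and returns ADP but *not* phosphate — phosphate is
  retained in biomass, as it is in nucleic acids. Since every other
  phosphate loop in the network is conservative (glycolysis ↔ maintenance
  ATPase, acetyl-CoA synthetase → PPi → diphosphatase → ATP synthase), the
  biomass optimum is exactly (phosphate supply)/8.3. The coefficients were
  chosen so the toy scenarios' predicted growth rates (0.241 and 0.193
  h$^{-1}$ at supplies of 2 and 1.6) land near the measured 0.24/0.19
  h$^{-1}$, and raising the mutant's supply back to 2 reproduces the
  observed ~25% growth recovery.
* **The PDC bypass and its ATP cost.** Pyruvate decarboxylase, NADP- and
  NAD-dependent acetaldehyde dehydrogenases, acetate transport and
  acetyl-CoA synthetase (ATP → AMP + PPi, cost settable via `atp_per_acs`)
  form the cytosolic route to mitochondrial acetyl-CoA. The TCA lump
  consumes mitochondrial phosphate (substrate-level phosphorylation); the
  glyoxylate lump regenerates redox without phosphate, so phosphate
  scarcity reroutes acetyl-CoA oxidation through the shunt — the truncated
  TCA picture.
* **Mitochondrial phosphate accounting.** The only mitochondrial phosphate
  producers are the diphosphatase and the cytosol→mitochondria transporter,
  so the phosphate ledger reproduces the diphosphatase-dominated supply
  split (98.99%/1.01% on the toy; the genome-scale study reports
  91.5%/8.1% — same structure, different network size).
* **A control-side isoprenoid cap.** The lumped network lacks the
  genome-scale biomass competition that keeps the control strain's HMG-CoA
  reductase flux small, so without a cap the parsimonious solution uses the
  mevalonate sink as a cheap carbon overflow valve. The packaged control
  scenario therefore caps it at the control pathway ceiling of 0.48 per 100
  glucose; the mutant scenarios fix 1.5, making the mutant > control MVA
  ordering structural.
* **Deactivation, not deletion.** `include_*` switches set bounds to zero
  instead of removing reactions, so a scenario directive addressing a
  switched-off module surfaces as infeasibility (the biologically
  meaningful outcome) rather than a missing-id error.

What the toy does **not** emulate: realistic stoichiometric coefficients or
elemental/charge balance of lumped steps, gene–protein–reaction mappings,
redox shuttles beyond a single NADH carrier, proton/charge translocation in
oxidative phosphorylation, and genome-scale degeneracy. Passing the toy
suite therefore demonstrates the correctness of the *pipeline mechanics*
(LP core, constraint staging, normalization, ledgers) and the qualitative
phosphate/PDC story, not quantitative agreement with any genome-scale
model. Quantitative targets (control capacity 0.48, mutant capacity 18.8,
2.2 under full constraints) require the genome-scale model file and the
study's supplementary constraint tables; `inst/extdata/genome_scale/`
ships editable templates for that workflow.

## Random models and the oracle

`generate_random_model()` draws small sparse networks (defaults: 5
metabolites, 8 reactions including one uptake and one secretion exchange)
with finite bounds and a zero-feasible box, so a finite optimum always
exists and vertex enumeration is exhaustive at
$\binom{n}{\mathrm{rank}(S)} 2^{\,n-\mathrm{rank}(S)}$ candidate bases.
Generation is seed-deterministic and restores the caller's RNG state. The
packaged verification sweep uses 100 seeds; at the default sizes it runs in
a few seconds.

## Known limitations

* The dense simplex is not meant for genome-scale models in routine use; a
  1500-reaction model solves, but slowly. The module boundary keeps the
  solver swappable.
* The transcriptomic rule maps expression folds directly to flux-bound
  folds; whether the original analysis adjusted them is not stated, so the
  rule is this package's explicit formalization.
* Up/down classification in `compare_scenarios()` defaults to a 1.1
  magnitude-ratio threshold; the analyses this mirrors state no threshold,
  so it is configurable.

```{r example, eval = FALSE}
toy <- generate_toy_model(toy_model_spec())
res <- run_scenarios(toy, toy_scenarios(toy))
res[, c("name", "status", "growth_predicted", "isoprenoid_flux")]
cofactor_ledger(toy, res$result[[3]]$dist, "pi_m")
```
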