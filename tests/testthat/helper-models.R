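# In-code fixtures: small hand-built models with known LP optima.

# EX_A (uptake <= 10) -> A -> B -> EX_B (objective). Optimum 10.
chain_model <- function(uptake = 10) {
  stoich_model(
    metabolites = tibble::tibble(id = c("A_c", "B_c"), compartment = "c"),
    reactions = tibble::tibble(
      id = c("EX_A", "R_AB", "EX_B"),
      stoichiometry = list(c(A_c = -1), c(A_c = -1, B_c = 1), c(B_c = -1)),
      lower_bound = c(-uptake, 0, 0),
      upper_bound = c(0, 1000, 1000)
    ),
    objective = "EX_B", id = "chain"
  )
}

# A splits to B (branch fixed at `ab`) and C; uptake 10; objective EX_C.
# With the A->B branch fixed at 4, EX_C optimum is 6.
branch_model <- function(ab_lower = 4, ab_upper = 4) {
  stoich_model(
    metabolites = tibble::tibble(id = c("A_c", "B_c", "C_c"), compartment = "c"),
    reactions = tibble::tibble(
      id = c("EX_A", "R_AB", "R_AC", "EX_B", "EX_C"),
      stoichiometry = list(c(A_c = -1), c(A_c = -1, B_c = 1),
                           c(A_c = -1, C_c = 1), c(B_c = -1), c(C_c = -1)),
      lower_bound = c(-10, ab_lower, 0, 0, 0),
      upper_bound = c(0, ab_upper, 1000, 1000, 1000)
    ),
    objective = "EX_C", id = "branch"
  )
}

toy_model_default <- function() generate_toy_model(toy_model_spec())

toy_scenarios_cached <- local({
  cache <- NULL
  function(model = toy_model_default()) {
    if (is.null(cache)) cache <<- toy_scenarios(model)
    cache
  }
})

minimal_sbml_text <- function() {
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1" fbc:required="false">',
    '<model id="mini" fbc:strict="true">',
    '<listOfCompartments><compartment id="c" name="cytosol" constant="true"/><compartment id="e" constant="true"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A_e" compartment="e" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>',
    '<species id="A_c" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false" fbc:chemicalFormula="C6H12O6"/>',
    '<species id="B_c" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>',
    '</listOfSpecies>',
    '<listOfParameters><parameter id="lb_m10" value="-10" constant="true"/><parameter id="zero" value="0" constant="true"/><parameter id="big" value="1000" constant="true"/></listOfParameters>',
    '<listOfReactions>',
    '<reaction id="EX_A" reversible="true" fast="false" fbc:lowerFluxBound="lb_m10" fbc:upperFluxBound="zero"><listOfReactants><speciesReference species="A_e" stoichiometry="1" constant="true"/></listOfReactants></reaction>',
    '<reaction id="T_A" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big"><listOfReactants><speciesReference species="A_e" stoichiometry="1" constant="true"/></listOfReactants><listOfProducts><speciesReference species="A_c" stoichiometry="1" constant="true"/></listOfProducts></reaction>',
    '<reaction id="R1" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big"><listOfReactants><speciesReference species="A_c" stoichiometry="1" constant="true"/></listOfReactants><listOfProducts><speciesReference species="B_c" stoichiometry="1" constant="true"/></listOfProducts></reaction>',
    '<reaction id="EX_B" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big"><listOfReactants><speciesReference species="B_c" stoichiometry="1" constant="true"/></listOfReactants></reaction>',
    '</listOfReactions>',
    '<fbc:listOfObjectives fbc:activeObjective="obj"><fbc:objective fbc:id="obj" fbc:type="maximize"><fbc:listOfFluxObjectives><fbc:fluxObjective fbc:reaction="EX_B" fbc:coefficient="1"/></fbc:listOfFluxObjectives></fbc:objective></fbc:listOfObjectives>',
    '</model></sbml>')
}
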