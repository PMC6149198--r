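# PDH test: force flux through mitochondrial pyruvate dehydrogenase on top
# of the transcriptomic constraints. The diffusion cap on mitochondrial
# pyruvate transport (10 per 100 glucose) cannot supply the forced PDH flux
# (60 per 100 glucose), so the scenario is infeasible by construction.
name: mutant_pdh_test
rates:
  strain: mutant
  glucose: -10
  ethanol: 10.68
  acetate: 1.5
  glycerol: 1
  growth_rate: 0.19
tala_lower_bound: 11
tala_reaction: TALA
isoprenoid_reaction: HMGCOAR
directives:
  - reaction: PYRt_cm
    kind: upper_bound
    value: 10
    source: diffusion
  - reaction: EX_pi
    kind: lower_bound
    value: -16
    source: phosphate_limitation
  - reaction: PDH
    kind: lower_bound
    value: 60
    source: pdh_test
  - reaction: HMGCOAR
    kind: fix
    value: 1.5
    source: target_fix
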