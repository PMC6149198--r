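# Mutant scenario with transcriptomic + transport/diffusion constraints.
# The transcriptomic bound on PDC is derived at run time from the control
# flux distribution (toy_transcriptomic_constraints.tsv) and prepended by
# toy_scenarios(); the diffusion cap on mitochondrial pyruvate transport and
# the isoprenoid target fix are listed here. Values per 100 glucose.
name: mutant_transcriptomic
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
  - reaction: HMGCOAR
    kind: fix
    value: 1.5
    source: target_fix
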