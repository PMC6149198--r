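# Mutant-like scenario: 11% lower ethanol secretion, higher acetate,
# phosphate-limited uptake, and the isoprenoid flux fixed at 1.5 units per
# 100 glucose (the chosen target value; provenance recorded in the scenario
# pipeline). Synthetic toy-scale values.
name: mutant
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
  - reaction: EX_pi
    kind: lower_bound
    value: -16
    source: phosphate_limitation
  - reaction: HMGCOAR
    kind: fix
    value: 1.5
    source: target_fix
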