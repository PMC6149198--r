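# Mutant transcriptomic scenario with raised extracellular phosphate:
# identical to mutant_transcriptomic except the phosphate uptake bound is
# relaxed. Growth increases; the fixed isoprenoid flux does not. Values per
# 100 glucose.
name: mutant_high_phosphate
rates:
  strain: mutant
  glucose: -10
  ethanol: 10.68
  acetate: 1.5
  glycerol: 1
  growth_rate: 0.24
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
    value: -20
    source: phosphate_raised
  - reaction: HMGCOAR
    kind: fix
    value: 1.5
    source: target_fix
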