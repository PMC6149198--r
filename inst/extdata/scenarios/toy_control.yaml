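# Control-like scenario for the synthetic central-carbon toy model.
# All directive values are per 100 units of glucose; rates are raw
# (mmol gDCW^-1 h^-1) toy-scale values, synthetic by construction.
name: control
rates:
  strain: control
  glucose: -10
  ethanol: 12
  acetate: 0.5
  glycerol: 1
  growth_rate: 0.24
tala_lower_bound: 11
tala_reaction: TALA
isoprenoid_reaction: HMGCOAR
directives:
  # Baseline cap on the unengineered isoprenoid pathway: without it the
  # lumped toy network would use the mevalonate sink as a carbon overflow
  # valve, which the control strain's low HMG-CoA reductase capacity rules
  # out. 0.48 per 100 glucose is the control-strain pathway ceiling.
  - reaction: HMGCOAR
    kind: upper_bound
    value: 0.48
    source: baseline_capacity
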