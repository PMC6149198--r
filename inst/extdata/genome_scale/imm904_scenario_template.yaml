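# Template for running the genome-scale scenarios on iMM904 (BiGG JSON or
# SBML/FBC; obtain the model file separately). The stated per-100-glucose
# settings are fixed: transaldolase lower bound 11, isoprenoid (HMGCOAR)
# target 1.5 for the mutant, experimental isoprenoid fold change 2.25.
# The measured uptake/secretion rates and the transcriptomic and
# transport/diffusion constraint tables come from the study supplement and
# must be filled in before use (values below are placeholders).
name: imm904_mutant_template
rates:
  strain: mutant_102a
  glucose: -999    # FILL IN: measured glucose uptake, mmol gDCW^-1 h^-1
  ethanol: 999     # FILL IN
  acetate: 999     # FILL IN
  glycerol: 999    # FILL IN
  growth_rate: 0.19
tala_lower_bound: 11
tala_reaction: TALA
isoprenoid_reaction: HMGCOAR
exchange_map:
  glucose: EX_glc__D_e
  ethanol: EX_etoh_e
  acetate: EX_ac_e
  glycerol: EX_glyc_e
directives:
  - reaction: HMGCOAR
    kind: fix
    value: 1.5
    source: target_fix   # chosen from control capacity 0.48 and fold 2.25
  # Append transcriptomic directives derived with
  # derive_transcriptomic_constraints() from the supplement fold-change
  # table, and the transport/diffusion directives from the supplement.
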