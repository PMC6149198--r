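# Editable pathway aggregates for the toy model; subsystem annotations
# differ between model versions, so aggregates are data, not code.
ppp: [TALA]
glycolysis: [GLYC_L]
pdc_bypass: [PDC, ALDD, ALDD_NAD, ACS]
tca: [PDH, TCA]
glyoxylate: [GLYOX]
mva: [HMGCOAR]
fermentation: [ADH]
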