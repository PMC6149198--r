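strain	glucose	ethanol	acetate	glycerol	growth_rate
control	-10	12	0.5	1	0.24
mutant	-10	10.68	1.5	1	0.19
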