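product	exchange	carbon_fraction
lactate	EX_lac	0.50
acetate	EX_ac	0.35
pyruvate	EX_pyr	0.15
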