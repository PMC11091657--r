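species	reaction_id	direction
glucose	EX_glc__D_e	uptake
succinic_acid	EX_succ_e	uptake
gaba	EX_gaba_e	secretion
glutamate	EX_glu__L_e	secretion
acetic_acid	EX_ac_e	secretion
growth	BIOMASS	secretion
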