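sustaining_proliferative_signaling	synthetic hallmark set	TP53	RB1	EIF1AX	mut_g01	mut_g02
chromatin_remodelling	synthetic hallmark set	MEN1	ARID1A	SMARCA4	KMT2C	mut_g03
evading_growth_suppressors	synthetic hallmark set	TP53	RB1	mut_g04	mut_g05
genome_instability	synthetic hallmark set	TP53	mut_g06	mut_g07	mut_g08
invasion_metastasis	synthetic hallmark set	mut_g09	mut_g10	mut_g11
inducing_angiogenesis	synthetic hallmark set	mut_g12	mut_g13
deregulating_energetics	synthetic hallmark set	mut_g14	mut_g15	mut_g16
immune_evasion	synthetic hallmark set	mut_g01	mut_g09	mut_g16
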