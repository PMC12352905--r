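HNF	HNF1A/HNF4G plus nine direct targets	HNF1A	HNF4G	AKR1C3	ANG	APOH	CLRN3	GAS2	METTL7B	MUC13	SGK2	UGT2B15
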