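AR_10_gene	10-gene AR-activity panel (editable default)	KLK3	KLK2	FKBP5	STEAP1	STEAP2	PLPP1	RAB3B	NDRG1	ALDH1A3	PMEPA1
AR_Hieronymus	Hieronymus-style androgen-response panel (editable default)	KLK3	KLK2	TMPRSS2	FKBP5	NKX3-1	PMEPA1	ABCC4	ACSL3	ZBTB10	HERC3	PTGER4	EAF2	MED28	NNMT	MAF	GNMT	CENPN	ELL2	ADAM7	C1orf116
AR	combined AR panel (union of the two)	KLK3	KLK2	FKBP5	STEAP1	STEAP2	PLPP1	RAB3B	NDRG1	ALDH1A3	PMEPA1	TMPRSS2	NKX3-1	ABCC4	ACSL3	ZBTB10	HERC3	PTGER4	EAF2	MED28	NNMT	MAF	GNMT	CENPN	ELL2	ADAM7	C1orf116
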