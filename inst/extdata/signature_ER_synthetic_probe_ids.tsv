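# receptor: ER
# cutoff: 0.43
# source: published signature coefficients; probe-set IDs are synthetic placeholders except 205225_at, 203497_at, 219197_s_at
probe_id	rho	gene_symbol
SYN_ADCY9_1_at	0.44	ADCY9
SYN_AMFR_1_at	0.44	AMFR
SYN_ANXA9_1_at	0.43	ANXA9
SYN_ANXA9_2_at	0.45	ANXA9
SYN_C6orf97_1_at	0.45	C6orf97
SYN_CA12_1_at	0.48	CA12
SYN_CA12_2_at	0.48	CA12
SYN_CA12_3_at	0.47	CA12
SYN_CA12_4_at	0.47	CA12
SYN_CA12_5_at	0.47	CA12
SYN_CELSR1_1_at	0.43	CELSR1
SYN_CYP2B6_CYP2B7P1_1_at	0.45	CYP2B6_CYP2B7P1
205225_at	0.50	ESR1
SYN_FAM176B_1_at	0.46	FAM176B
SYN_FAM176B_2_at	0.43	FAM176B
SYN_GAMT_1_at	0.45	GAMT
SYN_GATA3_1_at	0.45	GATA3
SYN_GATA3_2_at	0.48	GATA3
SYN_GATA3_3_at	0.47	GATA3
SYN_GFRA1_1_at	0.45	GFRA1
SYN_GREB1_1_at	0.46	GREB1
SYN_IL6ST_1_at	0.44	IL6ST
SYN_IL6ST_2_at	0.44	IL6ST
SYN_KCNK15_1_at	0.44	KCNK15
SYN_KDM4B_1_at	0.45	KDM4B
SYN_KDM4B_2_at	0.46	KDM4B
SYN_KDM4B_3_at	0.43	KDM4B
SYN_SCCPDH_1_at	0.43	SCCPDH
SYN_SCUBE2_1_at	0.46	SCUBE2
SYN_LIV1_1_at	0.46	LIV1
SYN_SSH3_1_at	0.44	SSH3
SYN_STC2_1_at	0.44	STC2
SYN_TBC1D9_1_at	0.43	TBC1D9
SYN_TFF1_1_at	0.44	TFF1
SYN_UNKNOWN_1_at	0.45	UNKNOWN
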