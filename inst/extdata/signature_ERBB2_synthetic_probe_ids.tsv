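# receptor: ERBB2
# cutoff: 0.35
# source: published signature coefficients; probe-set IDs are synthetic placeholders except 205225_at, 203497_at, 219197_s_at
probe_id	rho	gene_symbol
SYN_CDK12_1_at	0.38	CDK12
SYN_ERBB2_1_at	0.42	ERBB2
SYN_ERBB2_2_at	0.39	ERBB2
SYN_F2RL1_1_at	0.35	F2RL1
SYN_GRB7_1_at	0.43	GRB7
SYN_IDI1_1_at	0.37	IDI1
SYN_ITGB6_1_at	0.36	ITGB6
SYN_ITGB6_2_at	0.35	ITGB6
SYN_PERLD1_1_at	0.37	PERLD1
SYN_PERLD1_2_at	0.38	PERLD1
203497_at	0.45	PPARBP
SYN_PPARBP_2_at	0.39	PPARBP
SYN_SEC63_1_at	0.37	SEC63
SYN_STARD3_1_at	0.37	STARD3
SYN_TRIM26_1_at	0.36	TRIM26
SYN_DIRAS2_1_at	-0.36	DIRAS2
SYN_DUSP24_1_at	-0.36	DUSP24
SYN_UBTF_1_at	-0.36	UBTF
SYN_UNKNOWN_1_at	-0.37	UNKNOWN
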