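# receptor: PR
# cutoff: 0.38
# source: published signature coefficients; probe-set IDs are synthetic placeholders except 205225_at, 203497_at, 219197_s_at
probe_id	rho	gene_symbol
SYN_BBS1_1_at	0.40	BBS1
SYN_BBS1_2_at	0.40	BBS1
SYN_BCAM_1_at	0.40	BCAM
SYN_CA12_1_at	0.39	CA12
SYN_CA12_2_at	0.40	CA12
SYN_CASC1_1_at	0.39	CASC1
SYN_FAM176B_1_at	0.41	FAM176B
SYN_FAM176B_2_at	0.44	FAM176B
SYN_GAMT_1_at	0.40	GAMT
SYN_GATA3_1_at	0.39	GATA3
SYN_GATA3_2_at	0.41	GATA3
SYN_GFRA1_1_at	0.39	GFRA1
SYN_GLI3_1_at	0.39	GLI3
SYN_HPN_1_at	0.39	HPN
SYN_IL6ST_1_at	0.40	IL6ST
SYN_IL6ST_2_at	0.41	IL6ST
SYN_KDM4B_1_at	0.41	KDM4B
SYN_KDM4B_2_at	0.42	KDM4B
SYN_LAMB2_1_at	0.40	LAMB2
SYN_LRRC17_1_at	0.39	LRRC17
SYN_LZTFL1_1_at	0.39	LZTFL1
SYN_MAGED2_1_at	0.39	MAGED2
SYN_MAPT_1_at	0.39	MAPT
SYN_MAPT_2_at	0.40	MAPT
SYN_PDE4A_1_at	0.38	PDE4A
SYN_PGR_1_at	0.41	PGR
219197_s_at	0.44	SCUBE2
SYN_LIV1_1_at	0.38	LIV1
SYN_STARD13_1_at	0.39	STARD13
SYN_STC2_1_at	0.38	STC2
SYN_WDR19_1_at	0.40	WDR19
SYN_UNKNOWN_1_at	0.40	UNKNOWN
SYN_AURKA_1_at	-0.40	AURKA
SYN_AURKA_2_at	-0.38	AURKA
SYN_BUB1_1_at	-0.41	BUB1
SYN_C16orf61_1_at	-0.38	C16orf61
SYN_CCNA2_1_at	-0.40	CCNA2
SYN_CDC20_1_at	-0.40	CDC20
SYN_CDCA8_1_at	-0.39	CDCA8
SYN_CENPA_1_at	-0.38	CENPA
SYN_CENPN_1_at	-0.38	CENPN
SYN_CEP55_1_at	-0.39	CEP55
SYN_DBF4_1_at	-0.44	DBF4
SYN_DDX39_1_at	-0.39	DDX39
SYN_DLGAP5_1_at	-0.39	DLGAP5
SYN_GATAD2A_1_at	-0.41	GATAD2A
SYN_GTSE1_1_at	-0.38	GTSE1
SYN_HJURP_1_at	-0.39	HJURP
SYN_KIF2C_1_at	-0.41	KIF2C
SYN_KIF2C_2_at	-0.41	KIF2C
SYN_KPNA2_1_at	-0.41	KPNA2
SYN_LAD1_1_at	-0.41	LAD1
SYN_LPIN1_1_at	-0.40	LPIN1
SYN_MCAM_1_at	-0.39	MCAM
SYN_MELK_1_at	-0.40	MELK
SYN_MKI67_1_at	-0.39	MKI67
SYN_OR7E37P_1_at	-0.39	OR7E37P
SYN_PSME4_1_at	-0.42	PSME4
SYN_PTTG1_1_at	-0.40	PTTG1
SYN_SLC7A5_1_at	-0.40	SLC7A5
SYN_TTK_1_at	-0.40	TTK
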