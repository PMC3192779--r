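receptor	dataset	role	predictor	tn	fn	fp	tp
ER	GSE3494	training	signature	31	25	3	188
ER	GSE3494	training	best_probe	29	22	5	191
ER	GSE2034	validation	signature	68	26	9	183
ER	GSE7390	validation	signature	52	10	12	124
ER	GSE2603	validation	signature	41	2	0	54
ER	GSE20271	validation	signature	54	16	13	61
ER	GSE20194	validation	signature	103	17	11	147
ERBB2	GSE2603	training	signature	75	2	4	7
ERBB2	GSE2603	training	best_probe	78	1	2	7
ERBB2	GSE20271	training	signature	115	9	7	13
ERBB2	GSE20271	training	best_probe	115	13	7	9
ERBB2	GSE20194	validation	signature	218	14	1	45
ERBB2	GSE16446	validation	signature	61	5	1	26
PR	GSE3494	training	signature	45	31	16	159
PR	GSE3494	training	best_probe	29	17	32	173
PR	GSE20271	validation	signature	63	15	16	50
PR	GSE20194	validation	signature	107	22	50	99
PR	GSE9195	validation	signature	9	24	6	40
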