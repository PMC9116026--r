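gene	category	n_variants	cases	controls	lr_or	lr_ci_low	lr_ci_high	alpha	alpha_ci_low	alpha_ci_high	mix_or	mix_or_ci_low	mix_or_ci_high	constrained
ATM	noncarrier	NA	33351	37001	1	NA	NA	0	NA	NA	2.16	1.78	2.63	TRUE
ATM	outside_FAT_PIK	714	1259	1443	0.98	0.91	1.06	0.0041	0.001	0.02	2.16	1.78	2.63	TRUE
ATM	FAT_PIK_CADD1_4	171	317	333	1.10	0.94	1.29	0.055	0.03	0.12	2.16	1.78	2.63	TRUE
ATM	FAT_PIK_CADD5	103	239	162	1.64	1.33	2.02	0.54	0.41	0.68	2.16	1.78	2.63	TRUE
BRCA1	noncarrier	NA	34191	37996	1	NA	NA	0	NA	NA	10.61	7.92	14.21	TRUE
BRCA1	outside_RING_BRCT	479	811	856	1.01	0.92	1.12	0.0015	9.4e-05	0.025	10.61	7.92	14.21	TRUE
BRCA1	RING_BRCT_helix_low	79	120	103	1.18	0.90	1.55	1.0e-11	NA	NA	10.61	7.92	14.21	TRUE
BRCA1	RING_BRCT_helix_high	23	63	16	4.94	2.83	8.61	0.48	0.19	0.78	10.61	7.92	14.21	TRUE
BRCA2	noncarrier	NA	33006	36517	1	NA	NA	0	NA	NA	5.87	4.75	7.24	TRUE
BRCA2	helix_low	1160	2062	2323	0.98	0.92	1.04	5.1e-05	2.4e-09	0.52	5.87	4.75	7.24	TRUE
BRCA2	helix_high	62	114	94	1.28	0.96	1.70	0.11	0.04	0.25	5.87	4.75	7.24	TRUE
CHEK2	noncarrier	NA	34582	38480	1	NA	NA	0	NA	NA	1.75	1.47	2.08	FALSE
CHEK2	helix_low	157	403	363	1.26	1.08	1.46	0.33	0.25	0.43	1.75	1.47	2.08	FALSE
CHEK2	helix_high	121	265	177	1.73	1.42	2.11	0.95	0.86	0.98	1.75	1.47	2.08	FALSE
PALB2	noncarrier	NA	34622	38291	1	NA	NA	0	NA	NA	4.87	3.50	6.77	TRUE
PALB2	carriers	424	618	713	0.95	0.85	1.06	1.1e-04	1.6e-09	0.88	4.87	3.50	6.77	TRUE
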