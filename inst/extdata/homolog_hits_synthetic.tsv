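isoA	wrat_ctg_07	92	453	36	0	1	453	120500	121858	0.0	820
isoI	wrat_ctg_07	87	247	32	0	1	247	129900	130640	0.0	395
isoA	pd630_chr	96	453	18	0	1	453	2405000	2406358	0.0	880
isoI	pd630_chr	88	247	29	0	1	247	2412600	2413340	0.0	401
isoA	jvh1_ctg_12	89	453	49	0	1	453	88200	89558	0.0	790
isoI	jvh1_ctg_12	88	247	30	0	1	247	95100	95840	0.0	399
isoA	rha1_chr	26	410	298	12	10	420	5120000	5121230	2e-08	62
isoI	rha1_chr	31	210	140	6	20	230	810000	810630	5e-06	48
isoA	split_ctg_01	91	453	41	0	1	453	5000	6358	0.0	810
isoI	split_ctg_02	86	247	34	0	1	247	7000	7740	0.0	390
isoA	ery_ctg_03	45	300	160	8	50	350	40000	40900	1e-30	180
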