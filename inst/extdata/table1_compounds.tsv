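herbs	mol_id	name	mw	ob	dl	source	whitelisted
CS	MOL001002	Ellagic acid	302.2	43.06	0.43	tcmsp	FALSE
CS	MOL001918	Paeoniflorgenone	318.35	87.59	0.37	tcmsp	FALSE
CS	MOL001924	Paeoniflorin	480.51	53.87	0.79	tcmsp	FALSE
CS	MOL002714	Baicalein	270.25	33.52	0.21	tcmsp	FALSE
CS	MOL002776	Baicalin	446.39	40.12	0.75	tcmsp	FALSE
CS	MOL002883	Ethyl oleate (NF)	310.58	32.4	0.19	tcmsp	FALSE
CS	MOL004355	Spinasterol	412.77	42.98	0.76	tcmsp	FALSE
CS	MOL005043	Campest-5-en-3beta-ol	400.76	37.58	0.71	tcmsp	FALSE
CS	MOL006992	(2R,3R)-4-methoxyl-distylin	318.3	59.98	0.3	tcmsp	FALSE
CS	MOL006999	Stigmast-7-en-3-ol	414.79	37.42	0.75	tcmsp	FALSE
CS	MOL001921	Lactiflorin	462.49	49.12	0.8	tcmsp	FALSE
CS	MOL006990	(1S,2S,4R)-trans-2-hydroxy-1,8-cineole-B-D-glucopyranoside	332.44	30.25	0.27	tcmsp	FALSE
CS	MOL006994	1-O-beta-d-glucopyranosyl-8-o-benzoylpaeonisuffrone_qt	302.35	36.01	0.3	tcmsp	FALSE
CS	MOL006996	1-O-beta-d-glucopyranosylpaeonisuffrone_qt	332.38	65.08	0.35	tcmsp	FALSE
CS	MOL007004	Albiflorin	480.51	30.25	0.77	tcmsp	FALSE
CS	MOL007005	Albiflorin_qt	318.35	48.7	0.33	tcmsp	FALSE
CS	MOL007008	4-Ethyl-paeoniflorin_qt	332.38	56.87	0.44	tcmsp	FALSE
CS	MOL007012	4-O-methyl-paeoniflorin_qt	332.38	56.7	0.43	tcmsp	FALSE
CS	MOL007014	8-Debenzoylpaeonidanin	390.43	31.74	0.45	tcmsp	FALSE
CS	MOL007016	Paeoniflorigenone	318.35	65.33	0.37	tcmsp	FALSE
CS	MOL007018	9-Ethyl-neo-paeoniaflorin A_qt	334.4	64.42	0.3	tcmsp	FALSE
CS	MOL007022	Evofolin B	318.35	64.74	0.22	tcmsp	FALSE
CS	MOL007025	Isobenzoylpaeoniflorin	584.62	31.14	0.54	tcmsp	FALSE
DaH	MOL000096	(-)-Catechin	290.29	49.68	0.24	tcmsp	FALSE
DaH	MOL000471	Aloe-emodin	270.25	83.38	0.24	tcmsp	FALSE
DaH	MOL000554	Gallic acid-3-O-(6'-O-galloyl)-glucoside	484.4	30.25	0.67	tcmsp	FALSE
DaH	MOL002235	EUPATIN	360.34	50.8	0.41	tcmsp	FALSE
DaH	MOL002259	Physciondiglucoside	608.6	41.65	0.63	tcmsp	FALSE
DaH	MOL002268	Rhein	284.23	47.07	0.28	tcmsp	FALSE
DaH	MOL002280	Torachrysone-8-O-beta-D-(6'-oxayl)-glucoside	480.46	43.02	0.74	tcmsp	FALSE
DaH	MOL002281	Toralactone	272.27	46.46	0.24	tcmsp	FALSE
DaH	MOL002297	Daucosterol_qt	386.73	35.89	0.7	tcmsp	FALSE
DaH	MOL002251	Mutatochrome	552.96	48.64	0.61	tcmsp	FALSE
DaH	MOL002260	Procyanidin B-5,3'-O-gallate	730.67	31.99	0.32	tcmsp	FALSE
DaH	MOL002276	Sennoside E_qt	524.5	50.69	0.61	tcmsp	FALSE
DaH	MOL002288	Emodin-1-O-beta-D-glucopyranoside	432.41	44.81	0.8	tcmsp	FALSE
DaH	MOL002293	Sennoside D_qt	524.5	61.06	0.61	tcmsp	FALSE
DaH	MOL002303	Palmidin A	510.52	32.45	0.65	tcmsp	FALSE
DaH	MOL000472	Emodin	270.25	24.4	0.24	tcmsp	TRUE
DaH	MOL001729	Crysophanol	254.25	18.64	0.21	tcmsp	TRUE
DaH	MOL000476	Physcion	284.28	22.29	0.27	tcmsp	TRUE
DiH	MOL002819	Catalpol	362.37	5.07	0.44	tcmsp	TRUE
DiH	MOL003333	Acteoside	624.65	2.94	0.62	tcmsp	TRUE
DiH	MOL000732	Stachyose	666.66	3.25	0.59	tcmsp	TRUE
MDP	MOL000211	Mairin	456.78	55.38	0.78	tcmsp	FALSE
MDP	MOL007374	5-[[5-(4-Methoxyphenyl)-2-furyl]methylene]barbituric acid	312.3	43.44	0.3	tcmsp	FALSE
MDP	MOL007369	4-O-methylpaeoniflorin_qt	332.38	67.24	0.43	tcmsp	FALSE
MDP	MOL007382	Mudanpioside-h_qt 2	336.37	42.36	0.37	tcmsp	FALSE
MDP	MOL007384	Paeonidanin_qt	330.41	65.31	0.35	tcmsp	FALSE
SQ	MOL001494	Mandenol	308.56	42	0.19	tcmsp	FALSE
SQ	MOL001792	DFV	256.27	32.76	0.18	tcmsp	FALSE
SQ	MOL002879	Diop	390.62	43.59	0.39	tcmsp	FALSE
SQ	MOL005344	Ginsenoside rh2	622.98	36.32	0.56	tcmsp	FALSE
SQ	MOL007475	Ginsenoside f2	785.14	36.43	0.25	tcmsp	FALSE
SQ	MOL007476	Ginsenoside rb1	1109.46	6.29	0.04	tcmsp	TRUE
SQ	MOL005338	Ginsenoside Re	947.3	4.27	0.12	tcmsp	TRUE
SQ	MOL005341	Sanchinoside C1	801.14	10.04	0.28	tcmsp	TRUE
SQ	MOL007487	Notoginsenoside r1	933.27	5.43	0.13	tcmsp	TRUE
SCP	MOL001944	Marmesin	246.28	50.28	0.18	tcmsp	FALSE
SCP	MOL003542	8-Isopentenyl-kaempferol	354.38	38.04	0.39	tcmsp	FALSE
SCP	MOL003576	(1R,3aS,4R,6aS)-1,4-bis(3,4-dimethoxyphenyl)-1,3,3a,4,6,6a-hexahydrofuro[4,3-c]furan	386.48	52.35	0.62	tcmsp	FALSE
SCP	MOL003578	Cycloartenol	426.8	38.69	0.78	tcmsp	FALSE
MDP;SQ	MOL000098	Quercetin	302.25	46.43	0.28	tcmsp	FALSE
CS;DaH;SQ	MOL000358	Beta-sitosterol	414.79	36.91	0.75	tcmsp	FALSE
CS;DiH;MDP	MOL000359	Sitosterol	414.79	36.91	0.75	tcmsp	FALSE
MDP;SCP	MOL000422	Kaempferol	286.25	41.88	0.24	tcmsp	FALSE
CS;DiH;SQ	MOL000449	Stigmasterol	412.77	43.83	0.76	tcmsp	FALSE
CS;MDP	MOL000492	(+)-Catechin	290.29	54.83	0.24	tcmsp	FALSE
CS;MDP	MOL000874	Paeonol	166.19	28.79	0.04	tcmsp	TRUE
CS;MDP	MOL001925	Paeoniflorin_qt	318.35	68.18	0.4	tcmsp	FALSE
CS;MDP	MOL007003	Benzoyl paeoniflorin	584.62	31.14	0.54	tcmsp	FALSE
DL		Xanthine				animal_db	FALSE
DL		Guanosine				animal_db	FALSE
DL		Xanthinin				animal_db	FALSE
DL		Hyrcanoside				animal_db	FALSE
SNJ		Arginine				animal_db	FALSE
SNJ		Aspartic acid				animal_db	FALSE
SNJ		Alanine				animal_db	FALSE
DL;SNJ		4-Guanidino-1-butanol				animal_db	FALSE
DL;SNJ		Cholesterol				animal_db	FALSE
DL;SNJ		Guanidine				animal_db	FALSE
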