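herb	node	degree	betweenness
MDP;SQ	Quercetin	112	0.36958975
SNJ	Alanine	104	0.41797809
MDP;SCP	Kaempferol	39	0.06875802
DaH	Emodin	29	0.04544646
DL;SNJ	Guanidine	27	0.08907938
DL	Xanthinin	25	0.08396791
DL	Xanthine	24	0.08789741
CS	Baicalein	23	0.02318204
CS;MDP	Paeonol	20	0.02429964
CS;DaH;SQ	Beta-sitosterol	20	0.02791937
DL	Guanosine	19	0.06005265
SCP	8-Isopentenyl-kaempferol	18	0.02608771
DaH	Aloe-emodin	18	0.01960079
CS;DaH;SQ	Stigmasterol	18	0.03894191
DL;SNJ	Cholesterol	16	0.05001097
CS	Ellagicacid	15	0.01790131
SNJ	Aspartic acid	13	0.03120851
SCP	Marmesin	13	0.0165369
DL;SNJ	4-Guanidino-1-butanol	12	0.03705792
DaH	EUPATIN	12	0.01168363
CS;MDP	Benzoylpaeoniflorin	12	0.01694236
CS	Albiflorin_qt	12	0.0149345
SQ	Ginsenoside rb1	11	0.01531869
SQ	Ginsenoside rh2	10	0.01552107
CS	1-O-beta-d-glucopyranosyl-8-o-benzoylpaeonisuffrone_qt	10	0.00756521
CS	Evofolin B	10	0.01443392
SQ	Notoginsenoside r1	9	0.00950678
SQ	Ginsenoside f2	9	0.0087669
DaH	Mutatochrome	9	0.0191967
DaH	Procyanidin B-5,3'-O-gallate	9	0.02300249
CS	Albiflorin	9	0.00983057
DiH	Stachyose	8	0.00668771
DaH	Palmidin A	6	0.010557
CS	8-Debenzoylpaeonidanin	4	1.33E-02
CS	Paeoniflorin	4	0.00892285
Target	PTGS2	24	0.03392333
Target	PTGS1	21	0.0243207
Target	ESR1	17	0.04743098
Target	MAPT	15	0.02405041
Target	PRKACA	15	0.0125587
Target	AR	14	0.0546651
Target	PTAFR	14	0.01000789
Target	PGR	13	0.04286906
Target	SLC6A2	13	0.01380599
Target	SLC6A3	12	0.00778408
Target	ADRB2	9	0.06270829
Target	BAX	8	0.01594706
Target	ESR2	8	0.01052083
Target	F10	8	0.0115522
Target	PRKCA	8	0.07827366
Target	RXRA	8	0.01249876
Target	TOP2A	8	0.01135885
Target	CDK2	7	0.00778363
Target	F7	7	0.00821191
Target	TNF	7	0.01279629
Target	F2	6	0.00701019
Target	IL1B	6	0.06205608
Target	NOS2	6	0.01729864
Target	PRKCD	6	0.00681975
Target	VEGFA	6	0.01754771
Target	AKR1B1	5	0.02396875
Target	JUN	5	0.02537208
Target	MMP9	5	0.00770693
Target	NOS3	5	0.02534139
Target	NR3C2	5	0.0069026
Target	STAT1	5	0.01728485
Target	ADORA1	4	0.04165433
Target	ADRA2A	4	0.01897542
Target	CYP1A1	4	0.01430838
Target	GSTP1	4	0.02559893
Target	HIF1A	4	0.02506214
Target	PPARD	4	0.02353186
Target	TGFB1	4	1.03E-02
Target	VDR	4	8.61E-03
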