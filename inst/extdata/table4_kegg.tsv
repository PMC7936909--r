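pathway	id	input_number	background_number	p	p_adj
Metabolic pathways	hsa01100	37	1243	4.87E-06	0.000776
MAPK signaling pathway	hsa04010	11	255	0.000719	0.022949
Calcium signaling pathway	hsa04020	11	180	4.07E-05	0.004326
Oxytocin signaling pathway	hsa04921	9	158	0.00033	0.014855
Regulation of actin cytoskeleton	hsa04810	9	215	0.002595	0.063668
Endocytosis	hsa04144	9	260	0.008413	0.107348
Apoptosis	hsa04210	8	140	0.000686	0.022949
Focal adhesion	hsa04510	8	203	0.006202	0.104136
Neuroactive ligand-receptor interaction	hsa04080	8	278	0.032413	0.198843
Circadian entrainment	hsa04713	7	95	0.000356	0.014855
TNF signaling pathway	hsa04668	7	110	0.000812	0.02355
cGMP-PKG signaling pathway	hsa04022	7	167	0.007476	0.106674
cAMP signaling pathway	hsa04024	7	199	0.017613	0.156542
Tight junction	hsa04530	6	139	0.011322	0.124199
RNA degradation	hsa03018	5	77	0.004147	0.094488
Phosphatidylinositol signaling system	hsa04070	5	98	0.010704	0.121948
Leukocyte transendothelial migration	hsa04670	5	118	0.02151	0.171545
AMPK signaling pathway	hsa04152	5	125	0.026528	0.188053
Dopaminergic synapse	hsa04728	5	130	0.030533	0.1948
Cell adhesion molecules (CAMs)	hsa04514	5	146	0.045802	0.231919
Arginine and proline metabolism	hsa00330	4	50	0.005113	0.10411
Lysine degradation	hsa00310	4	52	0.005821	0.10411
Inositol phosphate metabolism	hsa00562	4	71	0.015938	0.154071
mRNA surveillance pathway	hsa03015	4	92	0.035408	0.200721
Fc gamma R-mediated phagocytosis	hsa04666	4	93	0.036571	0.201138
HIF-1 signaling pathway	hsa04066	4	103	0.049393	0.242404
Pyruvate metabolism	hsa00620	3	40	0.017749	0.156542
Cysteine and methionine metabolism	hsa00270	3	45	0.023739	0.180305
Nucleotide excision repair	hsa03420	3	47	0.026404	0.188053
Notch signaling pathway	hsa04330	3	48	0.027794	0.18808
Fanconi anemia pathway	hsa03460	3	55	0.038589	0.206572
Arginine biosynthesis	hsa00220	2	21	0.034827	0.200721
Glycosylphosphatidylinositol(GPI)-anchor biosynthesis	hsa00563	2	25	0.046729	0.232917
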