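kind	node1	node2
hc	CS	(+)-Catechin
hc	CS	(2R,3R)-4-methoxyl-distylin
hc	CS	1-o-beta-d-glucopyranosyl-8-o-benzoylpaeonisuffrone_qt
hc	CS	1-o-beta-d-glucopyranosylpaeonisuffrone_qt
hc	CS	baicalein
hc	CS	benzoylpaeoniflorin
hc	CS	beta-sitosterol
hc	CS	evofolin B
hc	CS	isobenzoylpaeoniflorin
hc	CS	lactiflorin
hc	CS	paeoniflorigenone
hc	CS	paeoniflorin_qt
hc	CS	paeonol
hc	CS	4-ethyl-paeoniflorin_qt
hc	CS	4-o-methyl-paeoniflorin_qt
hc	CS	8-debenzoylpaeonidanin
hc	CS	9-ethyl-neo-paeoniaflorinA_qt
hc	CS	albiflorin
hc	CS	albiflorin_qt
hc	CS	stigmasterol
hc	DaH	(-)-Catechin
hc	DaH	aloe-emodin
hc	DaH	beta-sitosterol
hc	DaH	crysophanol
hc	DaH	emodin
hc	DaH	EUPATIN
hc	DaH	mutatochrome
hc	DaH	physcion
hc	DaH	rhein
hc	DaH	toralactone
ct	1-O-beta-d-glucopyranosyl-8-o-benzoylpaeonisuffrone_qt	PTAFR
ct	1-o-beta-d-glucopyranosylpaeonisuffrone_qt	PTAFR
ct	4-ethyl-paeoniflorin_qt	PTAFR
ct	4-O-methylpaeoniflorin_qt	PTAFR
ct	4-o-methyl-paeoniflorin_qt	PTAFR
ct	9-ethyl-neo-paeoniaflorinA_qt	PTAFR
ct	albiflorin	PTAFR
ct	albiflorin_qt	PTAFR
ct	benzoylpaeoniflorin	PTAFR
ct	ginsenosidef2	PTAFR
ct	isobenzoylpaeoniflorin	PTAFR
ct	lactiflorin	PTAFR
ct	mutatochrome	PTAFR
ct	paeoniflorigenone	PTAFR
ct	Aloe-emodin	CASP3
ct	baicalein	CASP3
ct	beta-sitosterol	CASP3
ct	catalpol	CASP3
ct	emodin	CASP3
ct	ginsenosiderh2	CASP3
ct	kaempferol	CASP3
ct	quercetin	CASP3
tp	CACNA1H	MAPK signaling pathway
tp	CASP3	MAPK signaling pathway
tp	DUSP1	MAPK signaling pathway
tp	FGF14	MAPK signaling pathway
tp	FOS	MAPK signaling pathway
tp	GADD45G	MAPK signaling pathway
tp	MEF2C	MAPK signaling pathway
tp	NLK	MAPK signaling pathway
tp	NR4A1	MAPK signaling pathway
tp	SRF	MAPK signaling pathway
tp	TAOK2	MAPK signaling pathway
tp	CACNA1H	Calcium signaling pathway
tp	PTAFR	Calcium signaling pathway
tp	DRD1	Calcium signaling pathway
tp	NOS1	Calcium signaling pathway
tp	NOS2	Calcium signaling pathway
tp	PHKA2	Calcium signaling pathway
tp	RYR2	Calcium signaling pathway
tp	RYR3	Calcium signaling pathway
tp	SLC8A2	Calcium signaling pathway
tp	VDAC1	Calcium signaling pathway
tp	VDAC3	Calcium signaling pathway
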