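printed	canonical	note
NR4A11	NR4A1	likely typographic duplication of the trailing digit
Ellagicacid	Ellagic acid	missing space in key-node listing
Benzoylpaeoniflorin	Benzoyl paeoniflorin	spacing variant between compound library and key-node listing
9-ethyl-neo-paeoniaflorinA_qt	9-Ethyl-neo-paeoniaflorin A_qt	case and spacing variant
4-O-methylpaeoniflorin_qt	4-O-methyl-paeoniflorin_qt	hyphenation variant; printed as distinct nodes and kept distinct in graphs
ginsenosidef2	Ginsenoside f2	case and spacing variant
ginsenosiderh2	Ginsenoside rh2	case and spacing variant
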