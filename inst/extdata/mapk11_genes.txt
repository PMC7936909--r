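GADD45G
DUSP1
FOS
NR4A11
IL1RAP
MEF2C
NLK
SRF
CASP3
CACNA1H
TAOK2
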