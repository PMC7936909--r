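PTEN
CTH
PTGS2
PTAFR
FOS
NOS1
NOS2
PGR
MMP3
PON1
NEDD4
ACADSB
KL
CASP3
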