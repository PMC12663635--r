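# Synthetic stand-in for a third lysosomal database (toy gene list).
LAMP1
CTSD
CTSB
ARL8B
SNAPIN
LAMTOR1
LAMTOR3
VPS18
GNS
NPC1
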