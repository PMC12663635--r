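# Synthetic stand-in for a second lysosomal database (toy gene list).
LAMP1
LAMP2
CTSD
ARL8B
BORCS5
SNAPIN
BLOC1S1
LAMTOR1
RRAGC
VPS16
HEXB
GBA1
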