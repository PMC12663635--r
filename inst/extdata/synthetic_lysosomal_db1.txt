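# Synthetic stand-in for a lysosomal protein database (toy gene list).
# Replace with a real curated list (one symbol per line) for real analyses.
LAMP1
LAMP2
CTSD
CTSB
ARL8B
BORCS5
BORCS7
SNAPIN
BLOC1S1
BLOC1S2
LAMTOR1
LAMTOR2
RRAGA
VPS33A
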