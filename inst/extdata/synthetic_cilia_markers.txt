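# Synthetic stand-in for a curated ciliary gold-standard list (toy).
ARL13B
IFT43
TULP3
DZIP1
CBY1
CIBAR1
LRRC49
TCTN3
PKD2
EXOC3
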