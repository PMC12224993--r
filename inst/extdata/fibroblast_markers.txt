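COL1A1
COL1A2
COL3A1
DCN
LUM
PDGFRA
PDGFRB
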