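element,hydrophobicity
H,0.20
C,0.50
N,-0.50
O,-0.60
F,0.30
P,0.20
S,0.40
Cl,0.50
Br,0.60
I,0.70
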