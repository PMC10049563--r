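element,background,standard,toxicity
Zn,68.8,300,1
Cu,26.7,100,5
Cr,49.3,250,2
Pb,19.4,170,5
As,11.2,20,10
Hg,0.02,1.0,40
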