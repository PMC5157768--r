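study,effect,se
ANBP,-0.75,0.63
COOP,-1.61,3.30
EWPH,-0.90,5.56
HDFP,0.68,0.32
MRC1,-0.14,0.15
MRC2,0.06,0.24
STOP,0.53,2.04
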