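study,effect,se
ANBP,-6.85,0.78
COOP,-14.83,5.14
EWPH,-13.57,13.85
HDFP,-8.44,0.34
MRC1,-8.76,0.16
MRC2,-10.59,0.60
STOP,-17.65,6.38
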