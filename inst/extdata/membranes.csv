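label,mean_pore_diameter_nm,role
0.2 um,185,clarifier
0.05 um,50,fractionating
500 kDa,25,fractionating
300 kDa,15,fractionating
100 kDa,5,terminal
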