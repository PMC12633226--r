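mean_pore_diameter_nm,particle_diameter_nm,rejection
5,35,0.9
15,35,0.49
25,35,0.28
15,60,0.72
15,100,0.88
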