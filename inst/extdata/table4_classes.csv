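class,hri_mean,hri_sd,hri_min,hri_max
none,0.691,0.082,0.492,0.803
mild,0.809,0.149,0.621,1.094
moderate,1.003,0.128,0.771,1.153
severe,1.110,0.28,0.584,1.621
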