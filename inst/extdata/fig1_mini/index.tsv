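#t_s=0.920000
#d_f=0.110000
feature	neighbor	similarity
mk_01	rel_01	0.953016
mk_02	rel_02	0.971901
rel_01	mk_01	0.953016
rel_02	mk_02	0.971901
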