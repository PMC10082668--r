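marker	relative	high_group	replaced	similarity
mk_01	rel_01	A	FALSE	0.953016
mk_02	rel_02	A	FALSE	0.971901
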