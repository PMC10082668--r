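sample	group
A001	A
A002	A
A003	A
A004	A
B001	B
B002	B
B003	B
B004	B
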