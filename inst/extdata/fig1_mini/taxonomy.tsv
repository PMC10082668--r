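bg_01	k__Bacteria;p__P02;c__C01;o__O01;f__F01;g__Gbg01;s__
bg_02	k__Bacteria;p__P03;c__C01;o__O01;f__F01;g__Gbg02;s__
bg_03	k__Bacteria;p__P04;c__C01;o__O01;f__F01;g__Gbg03;s__
bg_04	k__Bacteria;p__P05;c__C01;o__O01;f__F01;g__Gbg04;s__
bg_05	k__Bacteria;p__P01;c__C01;o__O01;f__F01;g__Gbg05;s__
bg_06	k__Bacteria;p__P02;c__C01;o__O01;f__F01;g__Gbg06;s__
bg_07	k__Bacteria;p__P03;c__C01;o__O01;f__F01;g__Gbg07;s__
bg_08	k__Bacteria;p__P04;c__C01;o__O01;f__F01;g__Gbg08;s__
mk_01	k__Bacteria;p__P06;c__C01;o__O01;f__F01;g__Gmk01;s__
mk_02	k__Bacteria;p__P06;c__C01;o__O01;f__F01;g__Gmk02;s__
rel_01	k__Bacteria;p__P06;c__C01;o__O01;f__F01;g__Gmk01;s__
rel_02	k__Bacteria;p__P06;c__C01;o__O01;f__F01;g__Gmk02;s__
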