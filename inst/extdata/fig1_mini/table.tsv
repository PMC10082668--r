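#OTU ID	A001	A002	A003	A004	B001	B002	B003	B004
bg_01	0.27197702	0.24468088	0.25659881	0.31000014	0.39140480	0.21764473	0.21175355	0.21654750
bg_02	0.17724310	0.14739040	0.21049242	0.17113771	0.11692853	0.19008727	0.11252074	0.17048958
bg_03	0.12554900	0.19939968	0.13285350	0.17272765	0.18428647	0.09430114	0.28983807	0.24754997
bg_04	0.22442606	0.15776207	0.18968436	0.16512817	0.16393124	0.21631536	0.21386227	0.18678742
bg_05	0.06456356	0.08300006	0.04904610	0.07777659	0.03175036	0.14476290	0.10728153	0.03041562
bg_06	0.07400503	0.02973974	0.06647143	0.01704200	0.06651173	0.03962260	0.02093670	0.03571371
bg_07	0.03618505	0.11346621	0.08522848	0.05474274	0.04154383	0.06964576	0.03662020	0.11035842
bg_08	0.01856082	0.01498489	0.00360924	0.02204893	0.00261998	0.02712822	0.00663784	0.00059895
mk_01	0.00350459	0.00532065	0.00000000	0.00542007	0.00000000	0.00000000	0.00054910	0.00101607
mk_02	0.00398578	0.00425542	0.00601566	0.00397599	0.00102306	0.00049202	0.00000000	0.00052277
rel_01	0.00000000	0.00000000	0.00000000	0.00000000	0.00000000	0.00000000	0.00000000	0.00000000
rel_02	0.00000000	0.00000000	0.00000000	0.00000000	0.00000000	0.00000000	0.00000000	0.00000000
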