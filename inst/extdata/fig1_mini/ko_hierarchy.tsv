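ko	level2	level1
ko001	L2_01	L1_01
ko002	L2_01	L1_01
ko003	L2_01	L1_01
ko004	L2_02	L1_01
ko005	L2_02	L1_01
ko006	L2_02	L1_01
ko007	L2_03	L1_01
ko008	L2_03	L1_01
ko009	L2_03	L1_02
ko010	L2_04	L1_02
ko011	L2_04	L1_02
ko012	L2_04	L1_02
ko013	L2_05	L1_02
ko014	L2_05	L1_02
ko015	L2_05	L1_02
ko016	L2_06	L1_02
ko017	L2_06	L1_03
ko018	L2_06	L1_03
ko019	L2_07	L1_03
ko020	L2_07	L1_03
ko021	L2_07	L1_03
ko022	L2_08	L1_03
ko023	L2_08	L1_03
ko024	L2_08	L1_03
ko025	L2_09	L1_04
ko026	L2_09	L1_04
ko027	L2_09	L1_04
ko028	L2_10	L1_04
ko029	L2_10	L1_04
ko030	L2_10	L1_04
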