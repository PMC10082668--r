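feature_id	ko001	ko002	ko003	ko004	ko005	ko006	ko007	ko008	ko009	ko010	ko011	ko012	ko013	ko014	ko015	ko016	ko017	ko018	ko019	ko020	ko021	ko022	ko023	ko024	ko025	ko026	ko027	ko028	ko029	ko030
bg_01	0.223012	0.327599	0.048092	0.448348	0.579112	0.206850	0.481286	1.890928	0.776360	0.267148	0.499830	0.104270	0.195581	0.352566	0.322032	0.662297	1.250002	0.735472	1.824235	1.859178	1.367163	0.621412	0.735535	0.538598	1.442241	0.144247	0.112002	1.260513	1.999347	0.176046
bg_02	0.289873	0.622064	0.900039	0.694577	0.442295	1.774824	0.204552	0.095727	3.751595	0.527514	2.008826	0.299763	0.079919	0.191859	0.314910	0.152995	0.699473	0.493328	0.073021	0.498265	4.241391	0.455360	2.112698	0.239765	1.265379	0.542938	1.672439	0.693315	1.144369	0.126899
bg_03	0.069310	0.276400	0.495516	1.869445	0.525414	0.326298	0.025290	0.532913	0.236579	0.665618	2.415830	1.086506	0.297299	0.599140	0.684946	0.711661	0.752705	1.240819	0.342575	0.996754	1.019292	0.880522	2.707785	0.129129	0.142013	0.478790	1.969695	0.880320	1.441707	0.279636
bg_04	1.444138	1.093092	0.815698	0.113496	0.584116	0.539260	1.318188	0.617502	0.981902	1.039645	0.932183	0.239902	0.290468	2.559284	0.335592	1.325370	0.310705	0.524908	0.645630	1.321417	0.671134	4.187019	0.262629	0.828575	3.034460	1.458451	0.141460	1.275777	0.371759	1.625110
bg_05	0.240612	1.254715	3.003389	2.607324	0.253345	0.327677	1.767765	0.851725	1.419736	0.932760	0.466564	0.017212	0.699143	3.679447	0.028179	0.538231	0.459935	0.257930	0.064760	0.622241	5.390019	0.947062	0.557282	1.771773	0.310830	1.168199	0.404351	0.470762	1.551195	0.075979
bg_06	0.701617	0.561834	0.658295	0.595239	0.004265	0.504370	0.032936	0.258910	4.132339	0.377507	0.452559	0.713747	2.473871	0.028457	0.074240	0.183694	0.576744	0.256054	0.976802	0.076686	1.362666	2.282287	2.666438	2.797613	0.203677	0.155094	0.062726	1.774402	0.660084	0.092419
bg_07	0.310763	1.333770	2.037381	0.328273	1.999801	1.217077	0.036165	0.081147	0.475907	0.248947	1.825078	1.653231	1.936816	0.888609	0.044339	4.688972	0.299938	1.050706	0.381854	0.009351	3.012915	0.929323	4.328597	3.933736	1.496146	1.266235	0.268029	1.639075	3.271655	0.451405
bg_08	0.223903	0.350722	0.182646	0.656169	1.528843	0.646867	0.204883	0.007357	3.406262	0.127633	1.374422	0.624620	0.459804	0.349639	0.174665	0.195730	1.902354	0.738038	1.249560	0.196573	0.550721	1.955224	0.137937	2.003118	0.815164	1.106275	0.176710	0.460554	0.607947	1.699221
mk_01	2.983226	0.278352	1.118266	1.002674	0.440920	0.022228	0.039326	0.169175	0.202888	0.007877	1.145279	0.636299	0.777302	0.357627	1.993095	1.524727	1.117605	1.281971	0.121191	0.250635	0.181707	1.185170	0.942535	0.240380	0.214254	1.096558	0.824990	0.162903	1.560817	1.317951
mk_02	0.002123	2.408196	0.968660	0.038002	0.848775	1.772995	0.649769	1.252483	1.154857	0.981270	0.372803	1.657452	2.314439	2.225349	0.728879	0.064166	0.653781	0.883961	0.159727	0.298389	0.021373	0.155878	0.127538	0.862059	0.711990	1.344115	0.764840	0.238270	0.219098	0.042719
rel_01	2.867826	0.268111	1.144614	0.991907	0.436417	0.023246	0.039235	0.165717	0.208418	0.007729	1.192821	0.626935	0.759339	0.344087	2.018764	1.590099	1.102061	1.295192	0.122773	0.261224	0.186188	1.142681	0.918305	0.233837	0.215460	1.096386	0.836832	0.158919	1.537924	1.353636
rel_02	0.002079	2.398129	0.925443	0.039299	0.845072	1.821911	0.681255	1.212571	1.197670	1.021920	0.384267	1.686553	2.420377	2.185954	0.710069	0.064761	0.660865	0.917640	0.165571	0.300441	0.021142	0.162817	0.121445	0.839341	0.723574	1.292444	0.774565	0.231974	0.214873	0.041558
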