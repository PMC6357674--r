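id	group	country	longitude	latitude	altitude
L1_001	L1	Iran	46.9471602980047	37.5242770195473	2428.46023412421
L1_002	L1	Tajikistan	41.2451199321076	40.2308771694079	1858.86948476546
L1_003	L1	Turkey	43.006810920313	40.0085626398213	1643.5352534987
L1_004	L1	Azerbaijan	44.7733994740993	41.2222761560697	1688.76605387777
L1_005	L1	Iran	41.4784624828026	39.7040731029119	788.536692643538
L1_006	L1	Tajikistan	45.2237930502743	36.0521330167539	1388.84896570817
L1_007	L1	Iran	53.0871966553386	33.2861577132717	675.044331280515
L1_008	L1	Turkey	78.2112538486253	35.2520437866915	2203.06111350656
L1_009	L1	Iran	69.3571911160834	33.5729108203668	1803.89765924774
L1_010	L1	Turkey	61.2939169853926	33.1919064349495	2188.50540348794
L1_011	L1	Tajikistan	68.0499609168619	37.0253272368573	2261.68161001988
L1_012	L1	Tajikistan	69.1820758855902	39.3335865684785	658.109005098231
L2_001	L2	Azerbaijan	54.8258489556611	39.9271697376389	87.2020556777716
L2_002	L2	Azerbaijan	53.2622294723988	37.3840969630983	23.3528544008732
L2_003	L2	Iran	45.3881893232465	41.953192288056	33.0264576897025
L2_004	L2	Azerbaijan	54.7275281641632	41.7992786592804	15.5633446201682
L2_005	L2	Iran	55.0748409722	36.6980797848664	-16.1696866154671
L2_006	L2	Georgia	51.5023203846067	40.8988227348309	24.4381169229746
L2_007	L2	Georgia	53.8652583798394	35.9761030997615	1051.19245171547
L2_008	L2	Georgia	51.2551668407395	41.6315570415463	548.351280875504
L2_009	L2	Armenia	45.99861802347	41.7799366856925	225.701268054545
L2_010	L2	Armenia	44.7382288267836	37.519266026793	1171.56472947448
L2_011	L2	Iran	51.9580668117851	36.925781166181	481.188759431243
L2_012	L2	Armenia	49.1140030371025	38.1287677264772	1483.58711201698
WHT_001	wheat	USA			
WHT_002	wheat	USA			
WHT_003	wheat	USA			
WHT_004	wheat	USA			
WHT_005	wheat	USA			
HYB_F1_01	hybrid	Turkmenistan	65.1139052894432	39.8885216088966	604.125237697735
HYB_RIL_01	hybrid				
HYBG_01	hybrid	Georgia	45.0014120431151	41.3774913022062	365.493090869859
HYBG_02	hybrid	Georgia	44.0982318515889	42.5495209855726	972.341985022649
HYBG_03	hybrid	Georgia	42.0368361982983	41.3806835389696	549.485533544794
HYBG_04	hybrid	Georgia	46.1469126921147	41.057665410568	967.617547186092
HYBG_05	hybrid	Georgia	44.1107133412734	42.1292860168032	1091.39920426533
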