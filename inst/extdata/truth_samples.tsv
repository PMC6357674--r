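id	true_group	subpop	parent1	parent2
L1_001	L1	a		
L1_002	L1	a		
L1_003	L1	a		
L1_004	L1	a		
L1_005	L1	a		
L1_006	L1	a		
L1_007	L1	b		
L1_008	L1	b		
L1_009	L1	b		
L1_010	L1	b		
L1_011	L1	b		
L1_012	L1	b		
L2_001	L2	a		
L2_002	L2	a		
L2_003	L2	a		
L2_004	L2	a		
L2_005	L2	a		
L2_006	L2	a		
L2_007	L2	b		
L2_008	L2	b		
L2_009	L2	b		
L2_010	L2	b		
L2_011	L2	b		
L2_012	L2	b		
WHT_001	wheat			
WHT_002	wheat			
WHT_003	wheat			
WHT_004	wheat			
WHT_005	wheat			
HYB_F1_01	F1		L1_011	L2_002
HYB_RIL_01	RIL		L1_009	L2_011
HYBG_01	hybrid_lineage		L1_003	L2_003
HYBG_02	hybrid_lineage		L1_003	L2_003
HYBG_03	hybrid_lineage		L1_003	L2_003
HYBG_04	hybrid_lineage		L1_003	L2_003
HYBG_05	hybrid_lineage		L1_003	L2_003
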