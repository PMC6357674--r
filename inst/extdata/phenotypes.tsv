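id	leaf_rust	stem_rust_ttksk	hessian_fly
L1_001	R	S	
L1_002	R	R	S
L1_003	R	S	R
L1_004	S		S
L1_005	S	S	S
L1_006	R	R	R
L1_007	S	R	S
L1_008	R	R	R
L1_009	S	S	R
L1_010	S		S
L1_011	S	R	S
L1_012	S	R	R
L2_001	S	R	S
L2_002	S	R	S
L2_003	S	S	S
L2_004	R	S	R
L2_005	R	R	S
L2_006	S	S	S
L2_007	S		R
L2_008	S	S	R
L2_009	R	R	S
L2_010	S	S	S
L2_011	S	S	S
L2_012	S	S	R
WHT_001	S	S	S
WHT_002	S	S	S
WHT_003	S		S
WHT_004	S	S	
WHT_005	R	S	S
HYB_F1_01		S	S
HYB_RIL_01	S		S
HYBG_01	R	S	S
HYBG_02	S	S	
HYBG_03	R	S	S
HYBG_04	R	S	S
HYBG_05	S	S	R
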