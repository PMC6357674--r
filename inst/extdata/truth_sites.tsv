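role	site	allele	carriers
introgression	S00026	alt	WHT_001,WHT_003
introgression	S00114	alt	WHT_003,WHT_005
introgression	S00148	ref	WHT_002,WHT_005
introgression	S00184	ref	WHT_001,WHT_005
hybrid_private_fixed	S00019		
hybrid_private_fixed	S00027		
hybrid_private_fixed	S00050		
hybrid_private_fixed	S00123		
hybrid_private_fixed	S00146		
hybrid_private_fixed	S00153		
hybrid_private_segregating	S00159		
hybrid_private_segregating	S00191		
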