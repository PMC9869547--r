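mirna	gene
hsa-mir-155-5p	CDK4
hsa-mir-155-5p	ACTB
hsa-mir-155-5p	TNF
hsa-mir-155-5p	CAT
hsa-mir-155-5p	TP53
hsa-mir-155-5p	RAC2
hsa-mir-155-5p	RPLP0
hsa-mir-155-5p	CDKN1A
hsa-mir-155-5p	EEF2
hsa-mir-155-5p	CCL2
hsa-mir-17-5p	MAPK3
hsa-mir-17-5p	TNF
hsa-mir-17-5p	TLR7
hsa-mir-17-5p	ACTB
hsa-mir-17-5p	CDK4
hsa-mir-17-5p	TP53
hsa-mir-17-5p	CCL5
hsa-mir-17-5p	CDKN1A
hsa-mir-181a-5p	MAPK3
hsa-mir-181a-5p	ACTB
hsa-mir-181a-5p	CTSD
hsa-mir-181a-5p	TP53
hsa-mir-181a-5p	RPLP0
hsa-mir-181a-5p	CDKN1A
hsa-mir-181a-5p	CD4
hsa-mir-18a-5p	CDK4
hsa-mir-18a-5p	ACTB
hsa-mir-18a-5p	TP53
hsa-mir-18a-5p	RACK1
hsa-mir-18a-5p	CDKN1A
hsa-mir-18a-5p	EEF2
hsa-mir-92a-1-5p	CD74
hsa-mir-92a-1-5p	TP53
hsa-mir-92a-1-5p	CDKN1A
hsa-mir-92a-1-5p	EEF2
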