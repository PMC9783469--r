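label	region_name	artery	distance_level
1002	rostral anterior cingulate	ACA	1
1014	medial orbitofrontal	ACA	1
1016	parahippocampal	PCA	1
1035	insula	MCA	1
1034	transverse temporal	MCA	1
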