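10340919	T1	CHEMICAL	23	32	meloxicam
10340919	T2	GENE-Y	88	91	COX
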