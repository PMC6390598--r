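parameter	level	single	compound
sex	Male	23	1
sex	Female	34	6
smoking	No	31	6
smoking	Yes	26	1
genotype	L858R	38	4
genotype	exon19del	17	0
genotype	G719X	2	3
pstage	IA	37	2
pstage	IB	13	1
pstage	II-III	7	4
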