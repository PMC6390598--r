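patient	common_label	common_af	uncommon_label	uncommon_af	difference
2294	L858R	6.56	G598V	6.8	0.24
2312	L858R	13.3	E709G	13.9	0.6
3013	L858R	20.4	E709G	20.4	0
3290	L858R	20.2	E709G	18.4	1.8
1877	G719S	11.8	E709G	12.3	0.5
2233	G719S	30.9	R776H	48.1	17.2
2921	G719A	19.4	D761Y	65.9	46.5
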