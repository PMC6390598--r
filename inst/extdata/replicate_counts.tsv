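sample_id	arm	matched	orphan
1873	raw	6	5
2279	raw	4	7
3236	raw	8	3
1873	mbs	3	0
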