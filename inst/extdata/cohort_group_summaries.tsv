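parameter	group	n	mean	sd
age	single	57	66.4	9.6
age	compound	7	66.7	9.3
tumor_size_mm	single	57	22.5	8.9
tumor_size_mm	compound	7	33.7	23.3
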