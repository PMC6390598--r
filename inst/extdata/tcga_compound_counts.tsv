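genotype	compound	single
L858R	5	22
exon19del	2	26
G719X	3	2
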