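sample_id	mbs_calls	raw_calls
s01	1	8
s02	1	1
s03	1	2
s04	1	2
s05	2	4
s06	2	4
s07	2	3
s08	2	3
s09	2	3
s10	2	3
s11	2	3
s12	2	3
s13	2	2
s14	2	2
s15	2	2
s16	2	2
s17	3	4
s18	3	4
s19	3	4
s20	3	4
s21	3	3
s22	3	3
s23	3	3
s24	3	3
s25	3	3
s26	4	5
s27	4	5
s28	4	4
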