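haplotype	frequency	effect
00	0.1	0
01	0.3	0
10	0.15	0.111803398874989
11	0.45	0.111803398874989
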