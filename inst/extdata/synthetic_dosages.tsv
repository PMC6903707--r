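id	rs101	rs202	rs303	rs404	rs505
!effect_allele	C	T	A	G	G
s01	0	1	0.5	2	0
s02	1	1	0	2	0
s03	2	0	1	1	0
s04	1.5	2	1	0	1
s05	0.25	1	2	0	1
s06	1	NA	0	1	2
s07	0	0	1.25	1	0.1
s08	2	1	0	1	1.9
s09	1	2	1	0	1
s10	0.75	1	1	2	0
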