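##fileformat=VCFv4.2
##source=mrstrat synthetic fixture (10 samples x 5 variants)
##FORMAT=<ID=DS,Number=1,Type=Float,Description="Estimated alternate allele dosage">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s01	s02	s03	s04	s05	s06	s07	s08	s09	s10
1	10177	rs101	A	C	.	PASS	.	DS	0	1	2	1.5	0.25	1	0	2	1	0.75
2	20301	rs202	G	T	.	PASS	.	DS	1	1	0	2	1	.	0	1	2	1
3	30555	rs303	C	A	.	PASS	.	DS	0.5	0	1	1	2	0	1.25	0	1	1
4	41002	rs404	T	G	.	PASS	.	DS	2	2	1	0	0	1	1	1	0	2
5	52220	rs505	A	G	.	PASS	.	DS	0	0	0	1	1	2	0.1	1.9	1	0
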