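chrom	pos	ref	alt	pop_freq	dbsnp	cosmic
chr7	2100864	T	G	0	0	1
chr17	5700084	G	A	0	0	1
chr12	3900449	G	T	0	0	1
chr17	5700504	C	T	0	0	1
chr3	4700057	G	A	0	0	1
chr4	3700074	T	A	0.25	1	0
chr14	1200036	G	A	0	0	1
chr11	1500050	T	C	0.005	1	0
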