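##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3
1	1000	snpA	A	G	.	PASS	.	GT	0/0	0/1	1/1
1	2000	snpB	C	T	.	PASS	.	GT	0/0	0/0	1/1
2	1500	snpC	G	A,T	.	PASS	.	GT	0/0	0/1	1/2
2	3000	snpD	T	C	.	PASS	.	GT	1/1	1/1	0/1
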