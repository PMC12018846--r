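rs#	alleles	chrom	pos	strand	assembly#	center	protLSID	assayLSID	panelLSID	QCcode	S1	S2	S3
snpA	A/G	1	1000	+	NA	NA	NA	NA	NA	NA	AA	AG	GG
snpB	C/T	1	2000	+	NA	NA	NA	NA	NA	NA	CC	CC	TT
snpD	T/C	2	3000	+	NA	NA	NA	NA	NA	NA	CC	CC	TC
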