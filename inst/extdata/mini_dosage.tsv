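line	snp1	snp2
L1	0	2
L2	1	0
L3	2	NA
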