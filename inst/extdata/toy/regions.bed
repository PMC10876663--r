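chr1	1000	1100	r01	.	.
chr1	2000	2100	r02	.	.
chr1	3000	3100	r03	.	.
chr1	4000	4100	r04	.	.
chr1	5000	5100	r05	.	.
chr1	6000	6100	r06	.	.
chr1	7000	7100	r07	.	.
chr1	8000	8100	r08	.	.
chr1	9000	9100	r09	.	.
chr1	10000	10100	r10	.	.
chr1	11000	11100	r11	.	.
chr1	12000	12100	r12	.	.
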