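chr1	2000	2100	atac1	.	.
chr1	3000	3100	atac2	.	.
chr1	4000	4100	atac3	.	.
chr1	5000	5100	atac4	.	.
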