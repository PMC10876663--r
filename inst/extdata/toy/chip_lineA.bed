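chr1	10	50	a1	.	.
chr1	2000	2100	a2	.	.
chr1	3000	3100	a3	.	.
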