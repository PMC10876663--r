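chr1	1050	1550	g01	.	+
chr1	2050	2550	g02	.	+
chr1	3050	3550	g03	.	+
chr1	4050	4550	g04	.	+
chr1	5050	5550	g05	.	+
chr1	6050	6550	g06	.	+
chr1	7050	7550	g07	.	+
chr1	8050	8550	g08	.	+
chr1	9050	9550	g09	.	+
chr1	10050	10550	g10	.	+
chr1	11050	11550	g11	.	+
chr1	12050	12550	g12	.	+
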