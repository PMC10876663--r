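MEME version 4

ALPHABET= ACGT

Background letter frequencies
A 0.250000 C 0.250000 G 0.250000 T 0.250000

MOTIF TFA
letter-probability matrix: alength= 4 w= 8
0.909736 0.030088 0.030088 0.030088
0.030088 0.909736 0.030088 0.030088
0.030088 0.909736 0.030088 0.030088
0.030088 0.030088 0.909736 0.030088
0.030088 0.030088 0.030088 0.909736
0.909736 0.030088 0.030088 0.030088
0.909736 0.030088 0.030088 0.030088
0.030088 0.909736 0.030088 0.030088

MOTIF TFB
letter-probability matrix: alength= 4 w= 8
0.030088 0.030088 0.909736 0.030088
0.030088 0.030088 0.909736 0.030088
0.030088 0.909736 0.030088 0.030088
0.030088 0.030088 0.909736 0.030088
0.030088 0.030088 0.909736 0.030088
0.030088 0.909736 0.030088 0.030088
0.030088 0.030088 0.909736 0.030088
0.030088 0.909736 0.030088 0.030088

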