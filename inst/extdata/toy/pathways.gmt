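SET_A	na	g02	g03
SET_B	na	g07	g08
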