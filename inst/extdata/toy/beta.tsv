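id	T01	T02	T03	T04	N01	N02	N03	N04
r01	        0.3	        0.3	        0.3	        0.3	        0.8	        0.8	        0.8	        0.8
r02	        0.3	        0.3	        0.3	        0.3	        0.8	        0.8	        0.8	        0.8
r03	        0.3	        0.3	        0.3	        0.3	        0.8	        0.8	        0.8	        0.8
r04	        0.3	        0.3	        0.3	        0.3	        0.8	        0.8	        0.8	        0.8
r05	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5
r06	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5
r07	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5
r08	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5
r09	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5
r10	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5
r11	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5
r12	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5	        0.5
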