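id	T01	T02	T03	T04	T05	T06	N01	N02	N03	N04	N05	N06
g01	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10
g02	         40	         40	         40	         40	         40	         40	         10	         10	         10	         10	         10	         10
g03	         40	         40	         40	         40	         40	         40	         10	         10	         10	         10	         10	         10
g04	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10
g05	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10
g06	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10
g07	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10
g08	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10
g09	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10
g10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10
g11	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10
g12	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10
TFA	         60	         50	         45	         35	         30	         20	         10	         10	         10	         10	         10	         10
TFB	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10	         10
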