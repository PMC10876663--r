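id	KD01	KD02	KD03	KD04	CT01	CT02	CT03	CT04
g01	         10	         10	         10	         10	         10	         10	         10	         10
g02	         10	         10	         10	         10	         40	         40	         40	         40
g03	         10	         10	         10	         10	         40	         40	         40	         40
g04	         10	         10	         10	         10	         10	         10	         10	         10
g05	         10	         10	         10	         10	         10	         10	         10	         10
g06	         10	         10	         10	         10	         10	         10	         10	         10
g07	         10	         10	         10	         10	         10	         10	         10	         10
g08	         10	         10	         10	         10	         10	         10	         10	         10
g09	         10	         10	         10	         10	         10	         10	         10	         10
g10	         10	         10	         10	         10	         10	         10	         10	         10
g11	         10	         10	         10	         10	         10	         10	         10	         10
g12	         10	         10	         10	         10	         10	         10	         10	         10
TFA	         10	         10	         10	         10	         40	         40	         40	         40
TFB	         10	         10	         10	         10	         10	         10	         10	         10
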