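sample	group
KD01	knockdown
KD02	knockdown
KD03	knockdown
KD04	knockdown
CT01	control
CT02	control
CT03	control
CT04	control
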