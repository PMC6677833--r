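subtype	n
enterocyte	31
goblet-like	34
inflammatory	25
stem-like	90
TA	22
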