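source	target	weight
a	b	2
a	b	3
b	c	1.5
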