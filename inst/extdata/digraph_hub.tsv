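n1	n3
n2	n3
n3	n4
n3	n5
n4	n1
n5	n2
n4	n6
n6	n3
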