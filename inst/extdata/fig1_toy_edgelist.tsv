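protein1	protein2
b	g1
b	g2
b	g3
g2	w1
g2	w2
g2	w3
g3	w4
g3	w5
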