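start_pos	end_pos	domain_label
1	45	N-terminal
46	70	TM1/6
71	90	TMD-other
91	124	scaffold
125	145	TMD-other
146	215	EL2
216	245	TMD-other
246	270	EL3
271	300	TM1/6
301	350	TMD-other
351	395	EL4
396	450	scaffold
451	480	TMD-other
481	520	linker
521	556	TMD-other
557	599	C-terminal
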