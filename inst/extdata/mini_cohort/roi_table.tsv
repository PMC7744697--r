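id	source	x	y	z	label
1	a_priori	-23	0	0	synth_A
6	exploratory	-8	0	0	synth_B
15	confirmatory	7	0	0	synth_C
22	confirmatory	22	0	0	synth_D
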