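sample_id	haplogroup
HG01879	L0d2c1a1
HG02461	L0k1a1c
HG03052	C1b13c1
NA18853	C4a1a3a1
NA19098	B4a1a1b
NA19238	J2b1a
NA20274	D5a2a1+@16172
HG01530	M9a'b
HG02010	JT
HG02330	H3ag1
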