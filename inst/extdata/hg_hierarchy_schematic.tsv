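child	parent
L0	mt-MRCA
L1'2'3'4'5'6	mt-MRCA
L0a	L0
L0d	L0
L0k	L0
L0d2	L0d
L0d2c	L0d2
L0d2c1	L0d2c
L0d2c1a	L0d2c1
L0d2c1a1	L0d2c1a
L0k1	L0k
L0k1a	L0k1
L0k1a1	L0k1a
L0k1a1c	L0k1a1
L1	L1'2'3'4'5'6
L2'3'4'5'6	L1'2'3'4'5'6
L2'3'4'6	L2'3'4'5'6
L5	L2'3'4'5'6
L2	L2'3'4'6
L3'4'6	L2'3'4'6
L3'4	L3'4'6
L6	L3'4'6
L3	L3'4
L4	L3'4
L3b	L3
L3d	L3
M	L3
N	L3
M8	M
CZ	M8
C	CZ
Z	CZ
C1	C
C1b	C1
C1b13	C1b
C1b13c	C1b13
C1b13c1	C1b13c
C1d	C1
C1d1	C1d
C4	C
C4a	C4
C4a1	C4a
C4a1a	C4a1
C4a1a3	C4a1a
C4a1a3a	C4a1a3
C4a1a3a1	C4a1a3a
M9	M
M9a'b	M9
M9a	M9a'b
M9b	M9a'b
D	M
D4	D
D1	D4
D2	D4
D3	D4
D5	D
D5a	D5
D5a2	D5a
D5a2a	D5a2
D5a2a1	D5a2a
A	N
X	N
W	N
I	N
R	N
R0	R
HV	R0
H	HV
V	HV
H1	H
H3	H
H3ag	H3
H3ag1	H3ag
JT	R
J	JT
T	JT
J2	J
J2b	J2
J2b1	J2b
J2b1a	J2b1
U	R
U6	U
U6b	U6
U6b1	U6b
U6b2	U6b
U6b3	U6b
B	R
B2	B
B4	B
B4a	B4
B4a1	B4a
B4a1a	B4a1
B4a1a1	B4a1a
B4a1a1b	B4a1a1
B5	B
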