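	N	AFIB	SVTA	B	T
N	8644	70	0	8	34
AFIB	31	7183	0	1	0
SVTA	0	0	91	0	0
B	1	1	0	821	0
T	10	3	0	0	397
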