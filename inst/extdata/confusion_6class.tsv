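	N	AFIB	B	P	AFL	SBR
N	8707	43	6	0	0	0
AFIB	20	7156	2	0	37	0
B	1	0	822	0	0	0
P	0	0	0	1796	0	0
AFL	0	50	0	0	496	0
SBR	0	0	0	0	0	1796
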