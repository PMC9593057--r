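genotype	DREB1_A1	DREB1_A2	DREB1_B	DREB1_D	DREB1_D1	DREB1_D2	DTI
MISR1	1	1	1	1	1	1	2.8
SIDS12	0	1	1	1	1	1	3.17
SAKHA93	1	1	1	1	1	1	3.11
Gimmeiza-12	1	1	1	0	1	1	3.68
Shandweel-1	0	1	1	1	1	1	2.7
Beni Swief-5	0	1	1	1	1	1	3.08
Sohag-3	0	1	1	1	0	0	2.77
SIDS13	1	0	1	1	1	1	3.48
PI525434	0	0	0	1	1	1	3.53
Hutch	0	0	0	1	0	0	3.66
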