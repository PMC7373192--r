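label	Group	numOtus	Otu0001	Otu0002	Otu0003	Otu0004
0.03	spA_r1	4	900	60	40	0
0.03	spA_r2	4	880	70	50	0
0.03	spB_r1	4	10	20	0	970
0.03	spB_r2	4	15	25	0	960
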