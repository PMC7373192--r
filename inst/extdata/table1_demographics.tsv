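sex	age	race	pack_years	smoking_status	fev1_l	fev1_pct	fvc_l	fvc_pct	fev1_fvc
Female	25	White	0	Never	3.37	96	3.84	95	0.88
Male	68	White	0	Never	4.96	109	6.20	114	0.80
Female	61	White	0	Never	2.36	89	2.55	75	0.93
Female	73	White	0	Never	1.94	93	2.21	84	0.88
Female	59	White	0	Never	2.24	94	2.54	98	0.88
Male	22	White	0	Never	4.62	100	5.92	106	0.78
Female	24	Black	0	Never	2.72	82	2.98	82	0.91
Male	53	White	0	Never	3.95	111	4.17	94	0.95
Female	55	Black	20	Former	2.21	82	2.82	84	0.78
Female	55	Black	20	Former	2.30	91	2.51	91	0.92
Female	71	White	21	Former	1.72	85	1.97	79	0.88
Male	58	White	48	Former	3.30	98	4.16	98	0.79
Male	43	White	22.5	Current	4.41	119	5.34	116	0.83
Female	59	White	10.5	Current	2.59	81	3.00	86	0.86
Male	58	White	28.5	Current	3.50	89	4.59	95	0.76
Male	53	White	10.5	Current	3.02	83	3.46	77	0.87
Male	38	White	33	Current	4.74	108	5.63	106	0.84
Male	63	White	35	Current	3.12	88	3.83	87	0.81
Male	67	Black	25	Current	2.28	63	3.56	80	0.64
Female	59	White	20	Current	1.38	53	2.00	60	0.69
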