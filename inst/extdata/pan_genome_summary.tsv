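cluster_id	n_phages	lcb_min	lcb_max	n_core	core_pct	n_accessory	accessory_pct	pan
A1	17	16	16	28	22	98	78	126
A2	7	7	7	46	40	69	60	115
A3	4	4	4	62	73	23	27	85
B	6	6	6	27	33	54	67	81
C	10	6	10	86	37	147	63	233
D	19	14	17	72	39	115	61	187
E	18	16	17	184	58	133	42	317
F	13	5	5	197	59	136	41	333
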