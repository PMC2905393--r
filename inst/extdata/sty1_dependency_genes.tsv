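sty1_rank	gene	response_rank	sty1_level_log2	ratio_mut_wt	response_dependency	atf1_pcr1_rank
11	SPBC1683.01	217	2.94	0.54	Atf1	47
18	SPBC1105.13c	52	2.71	0.57	Atf1/Pcr1	9
18	SPBC1105.14|rsv2	114	2.71	0.57	Atf1	9
21	SPAC1751.01c|gti1	44	2.61	0.41	NA	90
23	SPAC343.12|rds1	178	2.53	0.44	Pcr1	33
25	SPAP8A3.04c|hsp9	102	2.49	0.35	Atf1/Pcr1	6
32	SPAC25B8.12c	NA	2.35	0.59	Pcr1	30
40	SPBC660.05	10	2.26	0.31	Atf1/Pcr1	4
43	SPCC794.12c|mae2	NA	2.21	0.56	NA	31
44	SPAC22F8.05	15	2.20	0.25	Atf1/Pcr1	50
48	SPAC328.03|tps1	87	2.16	0.39	NA	14
49	SPAC16A10.01	98	2.15	0.38	Atf1	15
49	SPAC24C9.15c|spn5	NA	2.15	0.38	NA	15
53	SPACUNK4.17	1	2.09	0.46	Atf1/Pcr1	26
59	SPACUNK4.15	68	2.03	0.47	Atf1/Pcr1	7
61	SPBC21C3.19	62	2.01	0.43	Atf1/Pcr1	70
63	SPBC29B5.01|atf1	175	1.99	0.55	Atf1	11
65	SPBPB21E7.08	NA	1.96	0.20	NA	69
69	SPAC23H3.15c	30	1.86	0.30	Atf1/Pcr1	36
69	SPAC25H1.02|jmj1	155	1.86	0.30	Atf1/Pcr1	36
70	SPCC757.07c|ctt1	137	1.85	0.59	Atf1	75
79	SPAC19D5.01|pyp2	9	1.73	0.58	Atf1/Pcr1	27
83	SPAC3A11.07	NA	1.67	0.52	NA	107
85	SPCC1322.07c	64	1.66	0.37	Atf1/Pcr1	32
85	SPCC1322.08|srk1	54	1.66	0.37	Atf1/Pcr1	32
89	SPAC13F5.03c	38	1.61	0.58	Atf1/Pcr1	41
106	SPBP4G3.02|pho1	NA	1.52	0.46	NA	137
135	SPBC713.11c|pmp3	NA	1.28	0.50	Atf1/Pcr1	96
141	SPCP31B10.06	61	1.25	0.43	Atf1/Pcr1	24
159	SPAC32A11.02c	56	1.18	0.56	Atf1/Pcr1	54
162	SPAC8C9.03|cgs1	71	1.16	0.46	Atf1/Pcr1	44
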