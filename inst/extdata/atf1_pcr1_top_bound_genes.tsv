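gene	atf1_level_log2	pcr1_level_log2	published_rank	cesr
SPCC320.03	3.479445	3.957555	1	TRUE
SPACUNK4.19	3.612945	3.77028	2	FALSE
SPBC1685.13	3.46139	3.850725	3	FALSE
SPBC660.05	3.37339	3.562445	4	TRUE
SPBC32F12.11|tdh1	3.30439	3.626775	5	FALSE
SPAP8A3.04c|hsp9	3.16572	3.74333	6	TRUE
SPACUNK4.15	3.156445	3.4805	7	TRUE
SPAC1039.11c	3.213335	3.35761	8	FALSE
SPBC1105.13c	3.1415	3.264165	9	TRUE
SPBC1105.14|rsv2	3.1415	3.264165	9	TRUE
SPCC63.14	3.198835	3.18039	10	TRUE
SPBC29B5.01|atf1	3.068055	3.25811	11	FALSE
SPCC1672.02c|sap1	3.242055	2.85228	12	FALSE
SPCC569.05c	2.856775	3.190445	13	FALSE
SPAC328.03|tps1	2.92722	3.0935	14	TRUE
SPAC16A10.01	2.95439	3.060225	15	TRUE
SPAC24C9.15c|spn5	2.95439	3.060225	15	FALSE
SPBC354.11c	2.95222	3.047945	16	FALSE
SPBC215.05|gpd1	2.93778	2.97672	17	TRUE
SPAC17A2.11	2.837775	2.890225	18	FALSE
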