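symbol	net_spectra	transcript_detected
Psma1	57	1
Psma2	57	0
Psma3	24	1
Psma4	67	0
Psma5	57	0
Psma6	72	1
Psma7	53	0
Psmb1	70	0
Psmb2	38	0
Psmb3	47	1
Psmb4	33	1
Psmb5	73	0
Psmb6	25	1
Psmb7	50	1
Psmb8	0	1
Psmc1	84	0
Psmc2	55	1
Psmc3	119	0
Psmc4	103	1
Psmc5	105	0
Psmc6	82	1
Psmd1	399	0
Psmd2	284	0
Psmd3	122	1
Psmd4	102	0
Psmd5	47	0
Psmd6	94	1
Psmd7	108	0
Psmd10	6	0
Psmd11	118	1
Psmd12	139	1
Psmd13	150	0
Psmd14	139	0
Psme1	21	0
Psme2	148	0
Psme3	42	0
Psme4	28	1
Psmf1	3	0
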