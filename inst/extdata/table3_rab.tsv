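symbol	net_spectra	transcript_detected
Rab1a	44	0
Rab1b	62	1
Rab2a	101	1
Rab2b	17	0
Rab3a	56	0
Rab3b	5	0
Rab3c	58	0
Rab4a	9	0
Rab4b	11	0
Rab5a	52	0
Rab5b	41	0
Rab5c	113	0
Rab6a	63	0
Rab6b	30	1
Rab7a	92	0
Rab8a	5	0
Rab9a	5	0
Rab9b	8	0
Rab10	83	0
Rab11b	163	0
Rab14	132	1
Rab21	27	0
Rab23	14	0
Rab31	20	0
Rab33a	11	0
Rab35	30	0
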