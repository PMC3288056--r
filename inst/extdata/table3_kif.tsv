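symbol	net_spectra	transcript_detected
Kif1a	76	1
Kif1b	9	0
Kif2	28	0
Kif3a	20	0
Kif3b	7	0
Kif5a	6	0
Kif5b	80	1
Kif5c	222	1
Kif21a	32	0
Kif21b	66	0
Kif22	0	1
Kifc2	0	1
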