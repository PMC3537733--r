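dataset	pos_pp	pos_pm	pos_mm	neg_pp	neg_pm	neg_mm	p_printed
SP50L	5	9	26	4	16	71	0.161
SP50L-20p	8	5	26	3	17	71	0.005
UP50L	4	15	67	7	48	146	0.454
UP50L-20p	5	12	69	6	57	138	0.022
UP70L	6	15	42	6	27	73	0.636
UP70L-20p	4	14	45	9	32	65	0.412
UP70L-20p25s	4	22	36	9	31	65	0.685
UP70L-20p35s	5	16	43	9	30	68	0.888
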