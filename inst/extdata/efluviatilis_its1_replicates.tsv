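condition	ITS1_len_253	ITS1_len_254	ITS1_sub_169_A	ITS1_sub_169_T
100ng_1	25.49	74.51	34	66
100ng_2	24.76	75.24	35	65
100ng_3	24.84	75.16	36	64
primers_2to1	25.41	74.59	34	66
primers_1to2	24.68	75.32	37	63
10ng	26.17	73.83	36	64
1ng	27.29	72.71	38	62
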