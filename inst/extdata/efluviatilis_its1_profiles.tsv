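sample	ITS1_len_252	ITS1_len_253	ITS1_len_254	ITS1_len_255	ITS1_sub_169_A	ITS1_sub_173_A	ITS1_sub_174_A	ITS1_sub_180_T	ITS1_sub_163_G
Pe1	0	6	35	59	74	0	49	41	0
Pe2	0	6	32	62	75	0	54	41	0
V1	0	82	10	8	79	0	0	0	0
V2	0	25	75	0	35	0	0	0	0
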