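sample	ITS2_sub_151_A	ITS2_sub_244_A	ITS2_sub_268_G	ITS2_len_321	ITS2_len_322	ITS2_len_323	ITS2_del_13	ITS2_del_247
Pe1	0	0	0	54	19	27	65	62
Pe2	0	0	0	48	38	13	70	64
V1	0	86	0	87	8	5	95	87
V2	0	0	0	20	25	55	32	33
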