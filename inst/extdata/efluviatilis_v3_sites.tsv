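sample	ITS1_len_252	ITS1_len_253	ITS1_len_254	ITS1_len_255	noise_pass
1	6	31	57	5	TRUE
2	7	30	56	6	TRUE
3	10	31	51	8	FALSE
4	8	32	54	6	TRUE
5	8	31	55	6	TRUE
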