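name	protospacer	edit_kind	inserted	deleted_len	position	pbs_len	hr_len
SYN1	GACGTTCTCGATGGTGCTAG	insertion	CATCATCACCACCATCAC	0	0	13	20
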