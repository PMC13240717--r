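protein_id	domain	start	end	e_value
p01	pullul_strch	420	780	1e-35
p01	AmyAc_bac_euk_AmyA	60	330	2e-28
p02	AmyAc_bac_euk_AmyA	45	380	4e-30
p02	CBM20	400	490	1e-12
p03	AmyAc_bac_CMD_like_2	35	360	6e-26
p03	Aamy_C	390	470	3e-15
p04	AmyAc_bac_euk_AmyA	50	340	1e-22
p06	FN3	10	100	5e-11
p07	GH31_N	20	210	2e-19
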