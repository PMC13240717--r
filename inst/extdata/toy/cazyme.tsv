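protein_id	hmmer	diamond	recommended
p01	GH13_32	GH13	GH13_32
p02	GH13;CBM20	GH13	GH13;CBM20
p03	GH13	GH13	GH13
p04	GH13	GH13	GH13
p05	GH13_2	GH13	GH13_2
p06	GH13	GH13	GH13
p07	GH31	GH31	GH31
p08	GT2	GT2	GT2
p09	-	-	-
p10	CBM20	CBM20	CBM20
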