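protein_id	call	probability
p01	SP	0.99
p02	SP	0.97
p03	TAT	0.93
p04	OTHER	0.02
p05	OTHER	0.11
p06	SP	0.95
p07	SP	0.88
p08	OTHER	0.05
p09	OTHER	0.01
p10	SP	0.91
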