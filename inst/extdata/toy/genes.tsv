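genome_id	contig_id	gene_index	protein_id	roles	at_contig_edge
gA	c1	0	p01	amylase	TRUE
gA	c1	1	p02	amylase	FALSE
gA	c1	2	p03	amylase	FALSE
gA	c1	3	p04		FALSE
gA	c1	4	p05		TRUE
gB	c1	0	p06		TRUE
gB	c1	1	p07		FALSE
gB	c1	2	p08		FALSE
gB	c1	3	p09		FALSE
gB	c1	4	p10		TRUE
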