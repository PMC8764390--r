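#superfamily	clade	n_families	n_rt_copies
Gypsy	athila	10	1668
Gypsy	crm	33	1049
Gypsy	del	10	673
Gypsy	galadriel	1	5
Gypsy	reina	17	75
Gypsy	tat	27	640
Copia	oryco1	16	122
Copia	oryco2	15	1268
Copia	retrofit	1	4
Copia	sire	2	7
Copia	tork	4	21
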