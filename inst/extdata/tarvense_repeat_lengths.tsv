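#class	length_mb
Genome_assembly	486.27
All_repeats	320.26
Satellites	0.02
Simple_repeats	3.46
Low_complexity	0.83
Small_RNA	1.11
Transposable_elements	315.15
ClassI_retrotransposon	281.64
LTR_retrotransposon	276.88
Gypsy	250.65
Copia	14.59
Unknown_LTR	11.64
NonLTR_retrotransposon	4.76
SINE	0.33
LINE	4.44
ClassII_DNA_transposon	10.69
Unclassified_interspersed	22.82
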