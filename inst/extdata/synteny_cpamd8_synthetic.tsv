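species	lineage	upstream	gene_present	downstream
human	primate	HAUS8	TRUE	SIN3B
chimpanzee	primate	HAUS8	TRUE	SIN3B
cow	laurasiatheria	HAUS8	TRUE	SIN3B
dog	laurasiatheria	HAUS8	TRUE	SIN3B
chicken	sauropsid	HAUS8	TRUE	SIN3B
xenopus	amphibian	HAUS8	TRUE	SIN3B
zebrafish	teleost	HAUS8	TRUE	SIN3B
mouse	rodent	HAUS8	FALSE	SIN3B
rat	rodent	HAUS8	FALSE	SIN3B
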