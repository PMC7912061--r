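name	delta_da	applicability
acetylation	42.01057	Nterm
carbamidomethylation	57.02146	C
deamidation	0.98402	NQ
dehydration	-18.01056	STED
oxidation	15.99491	MW
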