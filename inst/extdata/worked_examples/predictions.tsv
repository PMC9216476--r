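variant_key	cadd_phred	sift	mutation_taster	polyphen
OLI302_v1	28.9	deleterious	disease_causing	probably_damaging
OLI302_v2	21.2	absent	disease_causing	possibly_damaging
OLI474_v1	25.1	deleterious	disease_causing	probably_damaging
OLI474_v2	15	absent	absent	absent
OLI474_v3	12.4	tolerated	disease_causing	benign
OLI606_v1	24.3	deleterious	disease_causing	probably_damaging
OLI606_v2	18.1	absent	absent	possibly_damaging
OLI606_v3	22.7	deleterious	absent	probably_damaging
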