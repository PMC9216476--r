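gene_a	gene_b	confidence
G302A	G302B	0.91
DUOX2	TPO	0.8
TG	TPO	0.62
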