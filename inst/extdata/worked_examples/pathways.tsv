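gene	pathway_id	phenotype_relevant
MYH7	PW_CARDIAC_MUSCLE_CONTRACTION	TRUE
MRTFB	PW_SRF_SIGNALING	TRUE
NKX2-5	PW_HEART_DEVELOPMENT	TRUE
DUOX2	PW_THYROID_HORMONE_SYNTHESIS	TRUE
TG	PW_THYROID_HORMONE_SYNTHESIS	TRUE
TPO	PW_THYROID_HORMONE_SYNTHESIS	TRUE
G302A	PW_302_SHARED	TRUE
G302B	PW_302_SHARED	TRUE
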