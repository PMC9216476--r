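combination_id	present
OLI302	FALSE
OLI474	FALSE
OLI606	FALSE
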