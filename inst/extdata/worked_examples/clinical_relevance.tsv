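variant_key	relevant
OLI302_v1	TRUE
OLI302_v2	TRUE
OLI474_v1	TRUE
OLI474_v2	TRUE
OLI474_v3	TRUE
OLI606_v1	TRUE
OLI606_v2	FALSE
OLI606_v3	TRUE
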