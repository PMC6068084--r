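variant,tm_C
wild_type,76.8
R3,74.4
R5,71.1
K5,NA
D5,66.9
E5,69.5
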