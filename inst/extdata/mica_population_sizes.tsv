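population	n_samples
DE_Germany	48618
PL_Poland	11776
UK_British/Irish	2090
ZA_White	1989
ZA_Black	4085
CL_Non-Indigenous	4937
DE_Turkey	1823
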