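label	or	ci_low	ci_high
IARC	1.62	1.41	1.86
NCI	1.49	1.28	1.73
MDA	1.71	1.36	2.15
UK	1.47	1.18	1.83
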