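variant	koffS_per_min	konS_per_uM_min
Wild-type	33.0	5.82
G250E	350	36.8
E255K	127	12.2
E255V	122	5.82
T315I	29.7	5.82
T315M	16.2	12.8
Y253H-E255V	26.4	56.6
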