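variant	dG_active_kcal_per_mol	dG_active_se	dG_inactive_kcal_per_mol	dG_inactive_se	ddG_kcal_per_mol	ddG_se
Wild-type	0	0	0	0	0	0
G250E	-60.45	0.6	-62.66	0.1	-2.2	0.6
E255K	65.60	0.3	65.11	0.5	-0.5	0.6
E255V	57.12	0.2	56.77	0.2	-0.4	0.3
T315I	29.72	0.1	29.82	0.2	0.1	0.2
T315M	28.40	0.3	28.50	0.2	0.1	0.3
Y253H-E255V	56.66	0.4	57.06	0.3	0.4	0.4
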