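quantity	units	imatinib	ponatinib	dasatinib
ka	per_h	0.94	1.302	1.74
t_half_e	h	18	24	4
ke	per_h	0.0385	0.0289	0.173
dose	mg	400	45	180
molar_mass	g_per_mol	493.603	532.6	488.01
dose_umol	umol	810.4	84.49	368.8
Vd	L	435	1223	2502
F	fraction	1	1	1
tau	h	24	24	24
Gamma	nM	2112.46	70.65	163.73
alpha	dimensionless	6.28e9	3.72e13	1.37e18
epsilon	dimensionless	2.52	2	64
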