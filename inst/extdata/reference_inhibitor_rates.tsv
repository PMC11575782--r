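variant	RD_imatinib_nM	RD_ponatinib_nM	RD_dasatinib_nM	koffR_imatinib_per_min	koffR_ponatinib_per_min	koffR_dasatinib_per_min	konR_imatinib_per_nM_min	konR_ponatinib_per_nM_min	konR_dasatinib_per_nM_min
Wild-type	203.6	0.811	0.695	0.0590	0.00488	0.00233	6.01e-3	0.290e-3	3.35e-3
G250E	1338	4.63	3.00	0.0590	0.00488	0.0101	1.05e-3	0.0441e-3	3.35e-3
E255K	12021	6.66	3.90	0.0590	0.00488	0.0131	0.732e-3	0.0491e-3	3.35e-3
E255V	3651	11.1	2.57	0.0590	0.00488	0.00861	0.440e-3	0.0162e-3	3.35e-3
T315I	2721	1.86	40.5	0.0590	0.00488	0.136	2.63e-3	0.0217e-3	3.35e-3
T315M	1410	79.5	106	0.0590	0.00488	0.779	0.0614e-3	0.0419e-3	7.37e-3
Y253H-E255V	628.8	12.5	1.11	0.0590	0.00488	0.00372	0.391e-3	0.0938e-3	3.35e-3
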