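id	table	action	detail
rd_e255k_imatinib_decimal	reference_inhibitor_rates	scale_cell	RD_imatinib_nM E255K 12021 is a decimal-shift misprint; corrected to 1202.1 (the derivation formula gives 3174/2.641 = 1201.8)
konr_imatinib_ponatinib_transposed	reference_inhibitor_rates	swap_columns	konR columns for imatinib and ponatinib are transposed in print; corrected by swapping (off-rate/dissociation-constant consistency identifies the swap)
dasatinib_residence_off_rate	residence_times	note	printed dasatinib residence time 249 min is inconsistent with its printed off-rate 0.00233 per min (1/249 = 0.00402); downstream rate tables use the printed off-rate, i.e. an effective residence time of 429 min
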