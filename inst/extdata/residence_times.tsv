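drug	binding_mode	tR_min	koffR_per_min
imatinib	inactive_binder	17	0.059
ponatinib	inactive_binder	205	0.00488
dasatinib	active_binder	249	0.00233
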