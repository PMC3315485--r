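variant	dg_ns_kj	rseq_energy_bits	rseq_invivo_bits	rseq_over_dgns	reliable
WQR	2.70	3.03	3.26	1.21	TRUE
RQR	4.46	2.27	2.17	0.49	TRUE
RTR	3.30	2.46	2.52	0.76	TRUE
SAR	-9.98	0.80	4.66	-0.47	FALSE
TRR	2.40	2.44	6.00	2.5	TRUE
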