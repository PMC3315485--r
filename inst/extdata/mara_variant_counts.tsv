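binding_site	residues	tet20	tet30	total	codons	best	mitomi
GCA	RQR	2	3	5	1	TRUE	TRUE
GCA	RGR	1	3	4	1	FALSE	FALSE
GCA	RLR	2	1	3	2	FALSE	FALSE
GCA	RTR	1	0	1	1	FALSE	TRUE
GCA	GSR	3	1	4	2	FALSE	FALSE
GCA	GQR	1	1	2	2	FALSE	FALSE
GCA	GGR	1	0	1	1	FALSE	FALSE
GCA	WQR	1	0	1	1	FALSE	TRUE
GCA	WMR	2	0	2	1	FALSE	FALSE
GCA	TSR	1	0	1	1	FALSE	FALSE
GCA	TCK	1	0	1	1	FALSE	FALSE
GCA	SCR	1	0	1	1	FALSE	FALSE
GCA	FMR	1	0	1	1	FALSE	FALSE
GAA	SAR	1	0	1	1	FALSE	TRUE
GAA	SQR	15	15	30	3	TRUE	FALSE
GAC	RCR	3	0	3	1	FALSE	FALSE
GAC	RQR	13	0	12	1	FALSE	FALSE
GAC	TRR	2	0	2	1	TRUE	TRUE
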