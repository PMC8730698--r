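subunit	SC	dimer	monomer	RC47
PsbA	0.06	0.27	0.54	4.84
PsbB	0.07	0.25	0.67	4.81
PsbC	0.07	0.29	0.60	nd
PsbD	0.07	0.32	0.54	5.60
PsbE	0.09	0.27	0.64	6.05
PsbF	0.07	0.19	0.78	6.55
PsbJ	0.11	0.15	0.48	nd
PsbL	0.05	0.37	1.46	9.67
PBA1	0.10	0.14	0.30	6.28
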