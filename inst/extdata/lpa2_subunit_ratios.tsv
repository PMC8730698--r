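complex	subunit	ratio
ATP synthase	AtpA	1.27
ATP synthase	AtpB	1.30
ATP synthase	ATPC	1.28
ATP synthase	ATPD	1.08
ATP synthase	AtpE	1.52
ATP synthase	AtpF	1.52
ATP synthase	ATPG	1.28
ATP synthase	AtpI	1.72
Cytochrome b6f	PetA	1.01
Cytochrome b6f	PetB	0.93
Cytochrome b6f	PETC	1.09
Cytochrome b6f	PetD	0.68
Cytochrome b6f	PETM	1.52
Cytochrome b6f	PETO	0.96
PSII core	PsbA	0.29
PSII core	PsbB	0.29
PSII core	PsbC	0.23
PSII core	PsbD	0.30
PSII core	PsbE	0.49
PSII core	PsbF	0.55
PSII core	PsbH	0.67
PSII core	PsbJ	2.17
PSII core	PsbL	0.84
PSII core	PBA1	0.94
OEC	PSBO	0.55
OEC	PSBP1	0.61
OEC	PSBP2	0.46
OEC	PSBP3	1.08
OEC	PSBP4	0.81
OEC	PSBP6	0.61
OEC	PSBQ	0.54
OEC	PSBR	0.50
LHCII	LHCB4	1.20
LHCII	LHCB5	1.45
LHCII	LHCB7	1.79
LHCII	LHCBM1	1.41
LHCII	LHCBM3	1.25
LHCII	LHCBM5	1.27
LHCII	LHCBM6	1.27
LHCII	LHCBM8	1.20
LHCII	LHCBM9	0.94
PSI core	PsaA	0.93
PSI core	PsaB	0.71
PSI core	PsaC	0.88
PSI core	PSAD	1.06
PSI core	PSAE	1.15
PSI core	PSAF	1.03
PSI core	PSAG	0.70
PSI core	PSAH	1.04
PSI core	PsaJ	0.92
PSI core	PSAK	1.35
PSI core	PSAL	0.82
PSI core	PSAN	1.25
LHCA	LHCA1	1.10
LHCA	LHCA2	1.19
LHCA	LHCA3	0.88
LHCA	LHCA4	0.96
LHCA	LHCA5	1.04
LHCA	LHCA6	1.16
LHCA	LHCA7	1.03
LHCA	LHCA8	1.10
LHCA	LHCA9	1.25
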