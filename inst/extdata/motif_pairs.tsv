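motif_i	motif_j	observed_enrichment	reported_expected	reported_difference
V$AP1F	V$EBOX	1.38	1.07	0.31
V$IRFF	V$OVOL	0.91	0.81	0.10
V$AP1R	V$EBOX	1.18	1.09	0.09
V$AP1F	V$STAT	1.07	1.00	0.07
V$AP1R	V$STAT	1.07	1.00	0.07
V$AP1F	V$IRFF	0.99	0.93	0.06
V$NFKB	V$STAT	1.20	1.14	0.06
V$AP1F	V$AP1R	1.04	0.99	0.05
V$AP1F	V$CREB	1.03	0.99	0.04
V$IRFF	V$STAT	0.95	0.91	0.04
V$AP1F	V$NFKB	1.19	1.16	0.03
V$AP1F	V$MYBL	0.96	0.93	0.03
V$MYBL	V$NFKB	1.12	1.10	0.02
V$AP1R	V$IRFF	0.97	0.95	0.02
V$AP1R	V$MYBL	0.97	0.95	0.02
V$IRFF	V$MYBL	0.89	0.87	0.02
V$AP1R	V$CREB	1.02	1.01	0.01
V$MYBL	V$OVOL	0.82	0.82	0.00
V$AP1R	V$NFKB	1.18	1.19	-0.01
V$AP1R	V$OVOL	0.92	0.95	-0.03
V$MYBL	V$STAT	0.89	0.92	-0.03
V$OVOL	V$STAT	0.82	0.85	-0.03
V$EBOX	V$STAT	1.05	1.09	-0.04
V$AP1F	V$OVOL	0.82	0.87	-0.05
V$CREB	V$NFKB	1.11	1.16	-0.05
V$CREB	V$IRFF	0.87	0.93	-0.06
V$CREB	V$STAT	0.91	0.97	-0.06
V$IRFF	V$NFKB	1.01	1.09	-0.08
V$EBOX	V$IRFF	0.92	1.00	-0.08
V$CREB	V$MYBL	0.85	0.93	-0.08
V$EBOX	V$NFKB	1.17	1.25	-0.08
V$CREB	V$OVOL	0.77	0.87	-0.10
V$NFKB	V$OVOL	0.92	1.02	-0.10
V$EBOX	V$OVOL	0.81	0.93	-0.12
V$EBOX	V$MYBL	0.86	1.01	-0.15
V$CREB	V$EBOX	0.91	1.07	-0.16
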