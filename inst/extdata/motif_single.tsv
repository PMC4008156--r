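tf	motif	n_with	n_total	observed_pct	expected_prop	reported_fold	reported_p
AP1	V$AP1F	1380	4102	33.6	0.338	0.995	5.9e-01
MAFF	V$AP1R	3193	4102	77.8	0.766	1.016	3.1e-02
ATF3	V$CREB	3267	4102	79.6	0.801	0.994	7.7e-01
MYC	V$EBOX	2472	4102	60.3	0.561	1.074	3.8e-08
IRF6	V$IRFF	2696	4102	65.7	0.705	0.932	1.0
NFKB1	V$NFKB	2386	4102	58.2	0.498	1.168	3.9e-27
OVOL	V$OVOL	1467	4102	35.8	0.411	0.870	1.0
STAT	V$STAT	3191	4102	77.8	0.794	0.980	9.9e-01
MYB	V$MYBL	2873	4102	70.0	0.747	0.938	1.0
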