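tf_a	tf_b	tissue_class	level	n_promoters	n_a	n_b	n_peaks_a	n_peaks_b	both_observed	reported_expected	reported_fold
JUN	MYC	MET	promoter	4102	503	436	120679	19030	228	53.46	4.26
JUN	MYC	non_MET	promoter	4102	483	398	112929	80131	288	46.86	6.15
FOS	MYC	MET	promoter	4102	43	436	3282	19030	22	4.57	4.81
FOS	MYC	non_MET	promoter	4102	161	398	37162	80131	100	15.62	6.40
JUN	MYC	MET	peak	4102	796	305	120679	19030	152	0.43	350.51
JUN	MYC	non_MET	peak	4102	757	910	112929	80131	670	0.31	2145.60
FOS	MYC	MET	peak	4102	34	305	3282	19030	17	0.68	24.96
FOS	MYC	non_MET	peak	4102	251	910	37162	80131	253	0.31	804.10
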