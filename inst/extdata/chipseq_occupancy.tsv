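tf	tissue_class	n_peaks	promoters_with_peak	peaks_in_promoters	reported_promoter_rate_pct	reported_peak_rate_pct
JUN	not_cancer	75474	277	287	0.367	0.38
JUN	MET	120679	503	796	0.417	0.66
JUN	non_MET	112929	483	757	0.428	0.67
FOS	not_cancer	20695	119	103	0.575	0.50
FOS	MET	3282	43	34	1.310	1.04
FOS	non_MET	37162	161	251	0.433	0.68
MYC	MET	19030	436	305	NA	NA
MYC	non_MET	80131	398	910	NA	NA
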