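tf	mode	class_baseline	class_test	reported_fold	reported_p_op	reported_p	known_fold_anomaly	known_p_anomaly
JUN	promoter	not_cancer	MET	1.14	eq	0.0966	FALSE	FALSE
JUN	promoter	not_cancer	non_MET	1.17	eq	0.0463	FALSE	FALSE
JUN	promoter	MET	non_MET	1.05	eq	0.7083	TRUE	FALSE
FOS	promoter	not_cancer	MET	2.28	lt	0.0001	FALSE	FALSE
FOS	promoter	not_cancer	non_MET	0.75	eq	0.0226	FALSE	FALSE
FOS	promoter	MET	non_MET	0.33	lt	0.0001	FALSE	FALSE
JUN	peak	not_cancer	MET	1.73	lt	0.0001	FALSE	FALSE
JUN	peak	not_cancer	non_MET	1.76	lt	0.0001	FALSE	FALSE
JUN	peak	MET	non_MET	1.02	eq	0.7773	FALSE	TRUE
FOS	peak	not_cancer	MET	2.08	eq	0.0003	FALSE	FALSE
FOS	peak	not_cancer	non_MET	1.36	eq	0.0105	FALSE	FALSE
FOS	peak	MET	non_MET	0.65	eq	0.0252	FALSE	FALSE
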