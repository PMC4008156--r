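gene_set	set_size	database	term	n_hits	reported_pct	reported_p
oi_met	739	PubMed	cancer	521	70.5	< 0.01
oi_met	739	PubMed	breast_cancer	344	46.5	< 0.01
oi_met	739	PubMed	prostate_cancer	228	30.9	< 0.01
oi_met	739	PubMed	met_mesh	91	12.3	< 0.0001
oi_met	739	PMC	cancer	703	95.1	< 0.01
oi_met	739	PMC	breast_cancer	699	94.6	< 0.01
oi_met	739	PMC	prostate_cancer	679	91.9	< 0.01
oi_met	739	PMC	met_mesh	292	39.5	< 0.0001
oi_met_tf	52	PubMed	cancer	45	86.5	< 0.01
oi_met_tf	52	PubMed	breast_cancer	47	90.4	< 0.01
oi_met_tf	52	PubMed	prostate_cancer	36	69.2	< 0.01
oi_met_tf	52	PubMed	met_mesh	21	40.4	< 0.0001
oi_met_tf	52	PMC	cancer	48	92.3	< 0.01
oi_met_tf	52	PMC	breast_cancer	49	94.2	< 0.01
oi_met_tf	52	PMC	prostate_cancer	48	92.3	< 0.01
oi_met_tf	52	PMC	met_mesh	38	73.1	< 0.0001
hgnc_all	36973	PubMed	met_mesh	995	2.7	NA
hgnc_all	36973	PMC	met_mesh	1669	4.5	NA
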