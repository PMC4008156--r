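tf_group	gene	feature_id	level	model	fc_ovol1	fc_ovol2	fc_ovol12	reported_call
AP1	FOS	FOS	gene	BC	1.4	1.4	1.4
AP1	FOS	FOS	gene	PC	1.0	0.8	1.0
AP1	FOSB	FOSB	gene	BC	1.0	2.1	1.1	Up
AP1	FOSB	FOSB	gene	PC	0.7	0.5	0.4	Down
AP1	FOSB	NM_006732	isoform	BC	2.6	0.0	0.0	Switch
AP1	FOSB	NM_006732	isoform	PC	10.0	10.0	10.0	Switch
AP1	FOSB	NM_001114171	isoform	BC	0.9	2.3	1.1
AP1	FOSB	NM_001114171	isoform	PC	0.7	0.5	0.4
AP1	FOSL1	FOSL1	gene	BC	0.9	0.9	0.8
AP1	FOSL1	FOSL1	gene	PC	1.1	1.0	0.7
AP1	FOSL2	FOSL2	gene	BC	0.7	0.7	0.6	Down
AP1	FOSL2	FOSL2	gene	PC	0.8	1.2	1.1
AP1	JUN	JUN	gene	BC	1.0	0.9	0.8
AP1	JUN	JUN	gene	PC	0.5	0.5	0.5	Down
AP1	JUNB	JUNB	gene	BC	1.5	2.2	2.1	Up
AP1	JUNB	JUNB	gene	PC	1.2	1.9	1.4	Up
AP1	JUND	JUND	gene	BC	1.1	1.1	1.3
AP1	JUND	JUND	gene	PC	1.2	1.6	1.2	Up
STAT	STAT1	STAT1	gene	BC	1.1	1.3	1.0
STAT	STAT1	STAT1	gene	PC	1.0	1.4	2.0	Up
STAT	STAT1	NM_007315	isoform	BC	1.1	1.3	1.0
STAT	STAT1	NM_007315	isoform	PC	1.1	1.4	1.9	Up
STAT	STAT1	NM_139266	isoform	BC	1.2	1.3	1.1
STAT	STAT1	NM_139266	isoform	PC	0.8	1.7	2.2	Up
STAT	STAT3	STAT3	gene	BC	0.9	1.2	0.9
STAT	STAT3	STAT3	gene	PC	0.0	0.4	6.3	UpDown
STAT	STAT3	NM_139276	isoform	BC	0.5	1.6	0.9	UpDown
STAT	STAT3	NM_139276	isoform	PC	0.0	0.4	0.0	Switch
STAT	STAT3	NM_003150	isoform	BC	0.8	1.2	0.9
STAT	STAT3	NM_003150	isoform	PC	0.0	1.0	10.0
STAT	STAT3	NM_213662	isoform	BC	1.0	1.2	0.9
STAT	STAT3	NM_213662	isoform	PC	0.1	1.2	8.6	UpDown
NFKB	NFKB1	NFKB1	gene	BC	1.0	1.3	1.2
NFKB	NFKB1	NFKB1	gene	PC	1.0	1.1	1.0
NFKB	NFKB1	NM_003998	isoform	BC	1.0	1.3	1.2
NFKB	NFKB1	NM_003998	isoform	PC	1.3	1.1	1.2
NFKB	NFKB1	NM_001165412	isoform	BC	1.0	1.2	1.2
NFKB	NFKB1	NM_001165412	isoform	PC	0.8	1.0	0.9
NFKB	NFKB2	NFKB2	gene	BC	0.9	1.5	1.2	Up
NFKB	NFKB2	NFKB2	gene	PC	1.4	1.7	0.8	UpDown
NFKB	NFKB2	NM_001077494	isoform	BC	0.9	1.5	1.0	Up
NFKB	NFKB2	NM_001077494	isoform	PC	1.9	3.8	0.8	Up
NFKB	NFKB2	NM_002502	isoform	BC	0.7	1.6	0.9	Up
NFKB	NFKB2	NM_002502	isoform	PC	1.3	1.9	0.7	Up
NFKB	NFKB2	NM_001261403	isoform	BC	0.9	1.4	0.9
NFKB	NFKB2	NM_001261403	isoform	PC	1.4	1.4	0.8
NFKB	REL	REL	gene	BC	1.2	1.3	1.1
NFKB	REL	REL	gene	PC	1.6	2.2	1.6	Up
NFKB	RELA	RELA	gene	BC	1.0	1.1	1.1
NFKB	RELA	RELA	gene	PC	0.9	0.9	0.8
NFKB	RELA	NM_021975	isoform	BC	1.0	1.0	1.0
NFKB	RELA	NM_021975	isoform	PC	1.0	1.0	1.0
NFKB	RELA	NM_001145138	isoform	BC	1.0	1.1	1.1
NFKB	RELA	NM_001145138	isoform	PC	0.9	0.9	0.8
NFKB	RELB	RELB	gene	BC	0.8	1.5	1.1	Up
NFKB	RELB	RELB	gene	PC	1.3	2.4	1.0	Up
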