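category	item	count	printed_pct
gender	Female	86	86.9
gender	Male	13	13.1
stage	I	39	39.4
stage	II	33	33.3
stage	III	27	27.3
genetic_alteration	TP53	26	26.3
genetic_alteration	KRAS	20	20.2
kras_variant	G12C	3	3.0
kras_variant	G12D	6	6.1
kras_variant	G12V	10	10.1
kras_variant	G13C	1	1.0
genetic_alteration	SETD2	13	13.1
genetic_alteration	ERBB2	12	12.1
erbb2_variant	Exon20_insertion	7	7.1
genetic_alteration	ROS1	10	10.1
genetic_alteration	ARID1A	8	8.1
genetic_alteration	CDKN2A	8	8.1
genetic_alteration	MET	5	5.1
met_variant	Exon14_skipping	3	3.0
genetic_alteration	STK11	5	5.1
genetic_alteration	RET	5	5.1
genetic_alteration	APC	4	4.0
genetic_alteration	SMARCA4	4	4.0
genetic_alteration	PIK3CA	3	3.0
genetic_alteration	BRAF	2	2.0
genetic_alteration	KEAP1	2	2.0
genetic_alteration	RB1	2	2.0
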