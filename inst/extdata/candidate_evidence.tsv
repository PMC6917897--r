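list_id	gene_id	n_leading_edge_sets	mean_r	mem_s	mem_w	mot_s	mot_w
memory_cortical_pos	PRKCD	9	0.10	1	0	0	0
memory_cortical_pos	RAC1	9	0.07	1	0	0	0
memory_cortical_pos	HLA-DRB5	8	0.12	0	1	0	0
memory_cortical_pos	HLA-DRB1	8	0.09	0	1	0	0
memory_cortical_pos	HLA-DRB4	8	0.09	0	1	0	0
memory_cortical_pos	HCK	8	0.09	0	1	0	0
memory_cortical_pos	HLA-DRB3	8	0.08	0	0	0	0
memory_cortical_pos	LIMK1	7	0.13	1	0	0	1
memory_cortical_pos	CDC42	7	0.11	1	0	0	0
memory_cortical_pos	VAV1	6	0.15	0	1	0	0
memory_cortical_neg	HIST1H4A	23	-0.18	1	0	0	1
memory_cortical_neg	HIST1H4E	23	-0.17	1	0	0	1
memory_cortical_neg	HIST1H4H	23	-0.13	1	0	0	1
memory_cortical_neg	HIST1H4I	23	-0.12	1	0	0	1
memory_cortical_neg	HIST4H4	23	-0.11	1	0	0	1
memory_cortical_neg	HIST1H4J	23	-0.11	1	0	0	1
memory_cortical_neg	HIST1H4B	23	-0.10	1	0	0	1
memory_cortical_neg	HIST1H4K	23	-0.10	1	0	0	1
memory_cortical_neg	HIST1H4F	23	-0.09	1	0	0	1
memory_cortical_neg	HIST1H4D	23	-0.09	1	0	0	1
memory_subcortical_pos	CDK5	27	0.26	1	0	0	1
memory_subcortical_pos	NLGN1	26	0.51	1	0	0	0
memory_subcortical_pos	UNC13B	26	0.38	0	1	0	0
memory_subcortical_pos	RAB3A	25	0.40	1	0	1	0
memory_subcortical_pos	STX1A	24	0.57	1	0	0	0
memory_subcortical_pos	SYT12	23	0.44	0	1	0	0
memory_subcortical_pos	STX1B	22	0.45	0	1	0	0
memory_subcortical_pos	SNCA	21	0.44	1	0	1	0
memory_subcortical_pos	SYT1	21	0.39	1	0	0	1
memory_subcortical_pos	UNC13A	20	0.46	1	0	0	1
memory_subcortical_neg	RPL34	8	-0.54	0	1	0	0
memory_subcortical_neg	RPS12	8	-0.49	0	0	0	0
memory_subcortical_neg	RPS13	8	-0.47	0	1	0	0
memory_subcortical_neg	RPS15A	8	-0.44	0	1	0	0
memory_subcortical_neg	RPS29	8	-0.44	0	0	0	0
memory_subcortical_neg	RPL11	8	-0.44	0	1	0	0
memory_subcortical_neg	RPL37A	8	-0.44	0	0	0	0
memory_subcortical_neg	RPL10	8	-0.44	0	1	0	0
memory_subcortical_neg	RPS25	8	-0.44	0	1	0	0
memory_subcortical_neg	RPS27	8	-0.43	0	1	0	0
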