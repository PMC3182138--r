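id	it_control	it_drought	cb_control	cb_drought	log2_it	log2_cb	padj_it	padj_cb
miR166a	7796	12734	7334	21341	0.71	1.54	4e-177	0
miR171b	406	441	195	397	0.12	1.02	1	3e-09
miR171d	58	55	85	215	-0.08	1.33	1	2e-07
miR2111a	458	678	191	1105	0.57	2.53	5e-05	1e-106
miR2111b	241	340	107	333	0.50	1.64	0.48	4e-17
miR390b	52	33	110	34	-0.65	-1.69	1	8e-05
miR393	392	400	1120	258	0.03	-2.12	1	0
miR396b	4517	2958	5165	2411	-0.61	-1.10	0	0
miR482	19518	10487	49339	13487	-0.90	-1.87	0	0
vun_cand030	848	431	531	196	-0.98	-1.44	0	0
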