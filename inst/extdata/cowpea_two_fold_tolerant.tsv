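id	it_control	it_drought	cb_control	cb_drought	log2_it	log2_cb	padj_it	padj_cb
miR1515	489	1366	1415	2700	1.48	0.93	5e-63	4e-60
miR160a	437	877	1048	1102	1.01	0.07	3e-21	1
miR160b	13	244	139	178	4.18	0.35	9e-36	1
miR167b	1649	4488	7539	13930	1.44	0.89	2e-201	1e-288
miR171e	25	137	59	43	2.44	-0.45	4e-11	1
miR319b	1019	2638	685	1215	1.37	0.83	5e-109	2e-21
miR390a	2141	7242	3586	5308	1.76	0.57	0	3e-49
vun_cand009	582	1519	1025	1903	1.38	0.89	4e-63	4e-39
vun_cand015	62	297	61	96	2.25	0.66	2e-23	1
vun_cand020	4462	12349	6115	10535	1.47	0.78	0	6e-177
vun_cand033	478	172	96	113	-1.48	0.23	0	1
vun_cand048	746	263	0	2	-1.51	NA	0	1
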