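id	mature	it_control	it_drought	cb_control	cb_drought
vun_cand058	UUAAGCAGAAUGAUCAAAUUG	942	1546	3	0
vun_cand048	UGGUCUCUAAACUUUAGAAAUGAA	746	263	0	2
vun_cand036	UCAGAGGAAACAACACUUGUAC	59	23	0	0
vun_cand045	CGUGCUGAGAAAGUUGCUUCU	52	79	14	5
vun_cand053	GUAAUUGAGUUAAAAGGACUAUAU	43	6	0	2
vun_cand052	CGAGAGCCACUCGCCUAAGCGA	34	55	0	0
vun_cand055	CCACUGUAGUAGCUCUCGCUCA	30	40	0	0
vun_cand054	AGCAAGUUGAGGAUGGAGCUU	9	48	231	252
vun_cand014	UUCGGGAGUGAGAGCCAGUGA	3	0	56	5
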