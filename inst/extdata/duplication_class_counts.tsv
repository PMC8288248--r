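species	singleton	dispersed	proximal	tandem	wgd_segmental	unassigned	printed_total
Arabidopsis thaliana	78	307	20	57	295	0	757
Brassica napus	0	283	10	18	1414	369	2094
Brassica oleracea	8	220	15	15	459	0	717
Brassica rapa	11	257	13	28	761	1	1071
Theobroma cacao	19	269	40	38	170	1	537
Gossypium raimondii	14	380	32	60	491	6	983
Gossypium arboreum	44	389	28	56	410	41	968
Gossypium turneri	17	330	24	47	377	0	795
Gossypium barbadense	1	100	18	16	1732	29	1896
Gossypium darwinii	0	91	20	10	1772	5	1898
Gossypium hirsutum	0	90	17	22	1764	11	1904
Gossypium mustelinum	0	89	27	21	1804	5	1946
Gossypium tomentosum	0	89	13	23	1788	3	1916
Capsicum annuum CM334	15	360	34	40	65	0	514
Solanum lycopersicum	18	381	41	57	187	0	684
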