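family	species	copy_number	total_genes	printed_proportion
Brassicaceae	Arabidopsis thaliana	757	27655	2.74
Brassicaceae	Brassica napus	2094	101040	2.07
Brassicaceae	Brassica oleracea	717	35400	2.03
Brassicaceae	Brassica rapa	1071	46221	2.32
Malvaceae	Theobroma cacao	537	29452	1.82
Malvaceae	Herrania umbratica	521	18848	2.76
Malvaceae	Corchorus capsularis	368	29356	1.25
Malvaceae	Durio zibethinus	1096	35643	3.07
Malvaceae	Hibiscus syriacus (Gangneung)	2133	87603	2.43
Malvaceae	Gossypium raimondii	983	37505	2.62
Malvaceae	Gossypium arboreum	968	40960	2.36
Malvaceae	Gossypium turneri	795	38871	2.05
Malvaceae	Gossypium barbadense	1896	74561	2.54
Malvaceae	Gossypium darwinii	1898	78303	2.42
Malvaceae	Gossypium hirsutum	1904	75376	2.53
Malvaceae	Gossypium mustelinum	1946	74699	2.61
Malvaceae	Gossypium tomentosum	1916	78338	2.45
Solanaceae	Capsicum annuum CM334	514	34899	1.47
Solanaceae	Solanum lycopersicum	684	34688	1.97
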