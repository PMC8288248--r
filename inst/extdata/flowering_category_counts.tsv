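category	subcategory	printed_count
Aging		4
Ambient temperature		2
Circadian Clock		5
General process and autonomous pathway	Biotic stress	1
General process and autonomous pathway	Cell cycle and DNA replication	2
General process and autonomous pathway	Chromatin modifications	37
General process and autonomous pathway	Control of transcription	7
General process and autonomous pathway	mRNA & microRNA processing	18
General process and autonomous pathway	Multiple processes	1
General process and autonomous pathway	Protein stability control	7
General process and autonomous pathway	Unknown processes	1
Hormones		5
Photoperiodism, light perception, and signaling		34
Sugar		8
Vernalization		10
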