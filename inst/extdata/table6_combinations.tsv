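# Unrelated MS patients carrying at least two of the screened low-frequency
# variants. Genotype cells: het, hom, or empty (non-carrier).
patient_id	sex	onset_age	phenotype	C6orf10_rs16870005	CD86_rs11575853	EVI5_rs41286809	GC_rs76781122	IL2RA_rs12722600	MALT1_rs74847855	TET2_rs61744960	TOP3A_rs2230153	TRAF3_rs138943371	TYK2_rs12720355	WWOX_rs7201683
132ZM	F	20	RR							het	het
159ZM	M	26	RR							het	het
173ZM	F	31	RR							het	het
194ZM	F	31	RR				het	hom						het
27-WP3	M	31	SP	het			het
43-WP3	F	31	PP		het			het
155ZM	F	33	SP							het		het
51-WP3	M	33	SP	het						het
109ZM	F	37	SP		het	het
63-WP3	F	37	SP	het	het					het
115ZM	F	38	SP						het	het				het
69-WP3	M	40	SP				het		het
111ZM	F	41	RR	het				het		het
49-WP3	F	42	PP				het	het
57-WP3	M	42	SP	het				het				het
208ZM	F	44	RR					het						het
MS18	F	45	SP		het							hom
184ZM	M	47	SP					het						het
192ZM	F	48	RR	het				het
72-WP3	F	48	PP						het	het
204ZM	M	50	RR					het	het
MS07	M	NA	SP		het						het
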