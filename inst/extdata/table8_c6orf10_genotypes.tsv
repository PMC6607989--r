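# Genotypes of the C6orf10 3'-exon low-frequency variants in carrier
# patients of the unrelated MS cohort (long format: one row per carried
# variant).
patient_id	sex	onset_age	phenotype	aa_change	genotype
138ZM	F	21	RR	Ser454Xfr	het
221ZM	M	22	RR	Val559Leu	het
221ZM	M	22	RR	Glu561Asp	het
150ZM	F	25	RR	Ser389Xfr	hom
194ZM	F	31	RR	Gln385Glu	het
194ZM	F	31	RR	Thr429Ser	het
194ZM	F	31	RR	Gly477Val	het
106ZM	M	32	SP	Asp504Val	het
106ZM	M	32	SP	Asp522Asp	het
128ZM	F	32	RR	Glu506Val	het
109ZM	F	37	SP	Asp522Asp	het
115ZM	F	38	SP	Lys457stop	het
MS23	F	38	RR	Gly451stop	het
112ZM	F	41	RR	Lys557Ile	het
25-WP3	F	51	PP	Asp516Tyr	het
65-WP3	F	51	SP	Asp522Asp	het
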