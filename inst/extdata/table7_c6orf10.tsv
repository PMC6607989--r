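# Low-frequency variants found by Sanger sequencing of the C6orf10 3' exon
# region (chr6:32261295-32260757, 538 bp) in the 120-patient MS cohort.
# MAF columns are percents as published; "-" means no entry in that panel.
# Insertion/deletion alternate alleles use ins/del tokens as published.
#ms_cohort n_alleles=240
chrom	pos	variant_id	aa_change	prediction	ref	alt	maf_dbsnp150	maf_exac_nfe	maf_controls_gnomad_nfe	ms_alt_alleles	ms_maf_pct
6	32260761	-	Glu561Asp	neutral/damaging	C	G	-	-	-	1	0.42
6	32260769	-	Val559Leu	neutral/damaging	C	G	-	-	-	1	0.42
6	32260774	-	Lys557Ile	neutral/damaging	T	A	-	-	-	1	0.42
6	32260878	-	Asp522Asp	neutral/tolerated	G	A	-	-	-	3	1.25
6	32260898	-	Asp516Tyr	neutral/damaging	C	A	-	-	-	1	0.42
6	32260927	-	Glu506Val	neutral/damaging	T	A	-	-	-	1	0.42
6	32260933	rs766126891	Asp504Val	neutral/damaging	T	A	0.001	-	-	1	0.42
6	32261014	rs7751028	Gly477Val	deleterious/damaging	C	A	2.480	0.98	0.99	1	0.42
6	32261075	-	Lys457stop	damaging	T	A	-	-	-	1	0.42
6	32261084	-	Ser454Xfr	damaging	A	insG	-	-	-	1	0.42
6	32261093	-	Gly451stop	damaging	C	A	-	-	-	1	0.42
6	32261158	rs114543649	Thr429Ser	neutral/tolerated	G	C	2.479	0.98	0.99	1	0.42
6	32261277	-	Ser389Xfr	damaging	T	delT	-	-	-	2	0.83
6	32261291	-	Gln385Glu	neutral/tolerated	G	C	2.482	0.98	0.99	1	0.42
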