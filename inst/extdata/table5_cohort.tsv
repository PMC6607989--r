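# Candidate variants screened in the unrelated MS cohort (120 patients,
# 240 alleles). MAF columns are percents as published; p-value columns hold
# the published values verbatim ("-" where no test was published).
#tuscany_1000g n_alleles=214
#ms_cohort n_alleles=240
gene	chrom	pos	variant_id	ref	alt	transcript	exon	aa_change	consequence	ms_alt_alleles	ms_n_alleles	ms_maf_pct	maf_tuscany_1000g	maf_dbsnp150	maf_exac_nfe	maf_controls_gnomad_nfe	p_tuscany_1000g	p_dbsnp150	p_exac_nfe	p_controls_gnomad_nfe
ADAMTS3	4	73414590	-	T	C	ENST00000286657	3/22	Lys37Glu	missense	0	240	0	-	-	-	-	-	-	-	-
ANKRD55	5	55407449	rs77017041	A	G	ENST00000341048	10/12	Ser376Pro	missense	0	240	0	0.47	0.427	0.63	0.71	0.2871	0.3103	0.2174	0.1902
C6orf10	6	32261153	rs16870005	C	T	ENST00000533191	26/26	Ala431Thr	missense	9	240	3.75	1.4	1.250	1.43	0.85	0.0019	0.00049	0.0025	9.89e-07
CD86	3	121774281	rs11575853	A	G	ENST00000330540	5UTR	-	utr5	9	240	3.75	2.8	1.078	-	3.1	0.3723	6.1e-05	-	0.5612
EVI5	1	92979432	rs41286809	G	A	ENST00000540033	18/18	Phe749Phe	synonymous	2	240	0.83	0.47	1.116	1.55	1.61	0.4105	0.6768	0.3688	0.3391
GC	4	72669661	rs76781122	G	T	ENST00000504199	1/14	Met1Ile	start_lost	11	240	4.58	5.61	1.611	3.35	2.77	0.4895	0.00025	0.2883	0.0869
IL2RA	10	6054765	rs12722600	G	A	ENST00000379959	3UTR	-	utr3	19	240	7.92	4.21	1.777	-	0.87	0.0042	6.0e-13	-	<1.0e-20
MALT1	18	56367823	rs74847855	A	G	ENST00000348428	4/17	Arg217Gly	missense	11	240	4.58	1.9	3.734	4.28	4.20	0.0019	0.4877	0.8164	0.7672
MMEL1	1	2530169	rs147248515	G	T	ENST00000378412	12/24	Pro368Thr	missense	0	240	0	0	0.022	0.028	0.037	-	-	-	-
STAT4	2	191899319	-	A	G	ENST00000392320	18/24	Gln525Gln	synonymous	0	240	0	-	-	-	-	-	-	-	-
TET2	4	106156163	rs61744960	G	A	ENST00000540549	3/11	Gly355Asp	missense	20	240	8.33	5.6	2.614	3.77	3.69	0.0667	2.8e-08	0.00021	0.00014
TOP3A	17	18217958	rs2230153	G	A	ENST00000542570	1/19	Ala45Ala	synonymous	4	240	1.66	0.47	1.692	0.46	0.36	0.0067	0.9757	0.0057	0.00073
TRAF3	14	103371923	rs138943371	C	T	ENST00000347662	11/11	Ser478Ser	synonymous	3	240	1.25	0.47	0.245	0.30	0.36	0.0773	0.00164	0.0071	0.02133
TYK2	19	10472452	rs12720355	C	T	ENST00000525621	13/25	Ile651Ile	synonymous	4	240	1.66	1.4	0.962	1.38	1.45	0.7251	0.2634	0.7034	0.77887
WWOX	16	78458807	rs7201683	C	G	ENST00000566780	7/9	Leu216Val	missense	5	240	2.08	0.47	1.989	1.23	1.11	0.00026	0.9166	0.2304	0.150086
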