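# Low-frequency variants detected in the three MS families (family WES screen).
# MAF columns are percents as published; "-" means no entry in that panel.
# Carriers are "+"-separated member IDs. The row flagged ambiguous=TRUE is a
# published duplicate of the 4:73414590 record with an unprefixed carrier ID;
# it is excluded from analysis by default.
gene	chrom	pos	variant_id	ref	alt	consequence	maf_dbsnp150	maf_exac_nfe	maf_controls_gnomad_nfe	carriers	ambiguous
ADAMTS3	4	73178175	rs150270324	.	.	missense	0.926	1.34	1.12	A-I-2+A-II-3	FALSE
ADAMTS3	4	73414590	-	T	C	missense	-	0	0	B-I-1+B-II-3+B-II-4	FALSE
ADAMTS3	4	73414590	-	T	C	missense	-	0	-	II-3	TRUE
ANKRD55	5	55407449	rs77017041	A	G	missense	0.427	0.63	0.71	C-I-2+C-II-3	FALSE
BTNL2	6	32363893	rs28362679	.	.	missense	1.825	-	0	B-I-1+C-I-1+C-I-2	FALSE
C6orf10	6	32261153	rs16870005	C	T	missense	1.250	1.43	0.85	B-I-2+B-II-3	FALSE
GC	4	72669661	rs76781122	G	T	missense	1.611	3.35	2.77	B-I-2+B-II-3	FALSE
MALT1	18	56367823	rs74847855	A	G	missense	3.734	4.28	4.20	B-I-2+B-II-3+B-II-4	FALSE
MMEL1	1	2530169	rs147248515	G	T	missense	0.022	0.028	0.037	B-I-2+B-II-3	FALSE
TET2	4	106156163	rs61744960	G	A	missense	2.641	3.77	3.69	B-I-2+B-II-3+C-I-2+C-II-3+A-I-1+A-II-4	FALSE
WWOX	16	78458807	rs7201683	C	G	missense	1.989	1.23	1.11	B-I-2+B-II-3+B-II-4+C-I-2	FALSE
EVI5	1	92979432	rs41286809	G	A	synonymous	1.116	1.55	1.61	C-I-2+C-II-3+A-I-1+A-II-3+A-II-4	FALSE
GC	4	72620788	rs76803094	.	.	synonymous	1.799	2.56	2.14	B-I-1+B-II-3+B-II-4	FALSE
GEMIN2	14	39587220	rs150986614	.	.	synonymous	0.251	0.37	0.37	A-I-2+A-II-3+A-II-4	FALSE
STAT4	2	191899319	-	A	G	synonymous	-	-	-	C-I-2+C-II-3	FALSE
TRAF3	14	103371923	rs138943371	C	T	synonymous	0.245	0.30	0.36	C-I-2+C-II-3	FALSE
TOP3A	17	18217958	rs2230153	G	A	synonymous	1.692	0.46	0.36	C-I-2+C-II-3+A-I-2	FALSE
TYK2	19	10472452	rs12720355	C	T	synonymous	0.962	1.38	1.45	C-I-2+C-II-3	FALSE
CD86	3	121774281	rs11575853	A	G	utr5	1.078	-	3.1	B-I-2+B-II-3+C-I-1	FALSE
IL2RA	10	6054765	rs12722600	G	A	utr3	1.777	-	0.87	B-I-2+B-II-3+C-I-1+C-II-3	FALSE
RRAS2	11	14300827	-	.	.	utr3	-	-	-	B-I-2+B-II-4	FALSE
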