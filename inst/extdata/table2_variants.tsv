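# Eleven key pathogenic / likely pathogenic / predicted deleterious variants
# with their panel genes, identifiers, HGVS descriptions, clinical
# assertions and in-silico annotations. Genomic coordinates are synthetic
# placeholders (transcript c. position on the gene's chromosome): the source
# table reports variants at HGVS resolution only. Per-tool calls and CADD
# values are consensus-consistent reconstructions of the published
# damaging / neutral verdicts; allele frequencies for the rs/COSV entries
# are representative ultra-rare values (PopMax < 0.1%), and the novel
# entries carry none.
sample_id	gene	panel	variant_id	transcript_id	hgvs_c	hgvs_p	consequence	impact	canonical	chrom	pos	ref	alt	zygosity	af_1000g	gnomad_exome_af	gnomad_genome_af	subpop_afs	sift	polyphen	fathmm	mutation_taster	mutation_assessor	provean	cadd_phred	sift_indel	clinvar	uniprot
P01	ANK2	CA	COSV100003794	ENST00000357077.9	c.2693G>T	p.Ser898Ile	missense_variant	MODERATE	1	chr4	2693	G	T	het		7.9e-06		NFE:1.4e-05	deleterious	probably_damaging	D	D	M	D	24.1		-	-
P02	KCNQ1	CA	rs199472737	ENST00000155840.12	c.877C>T	p.Arg293Cys	missense_variant	MODERATE	1	chr11	877	C	T	het		1.2e-05		NFE:2.1e-05,SAS:3.0e-05	deleterious	probably_damaging	D	D	M	D	26.3		US	LP/P
P03	LDLR	FH	rs879254847	ENST00000558518.6	c.1255T>G	p.Tyr419Asp	missense_variant	MODERATE	1	chr19	1255	T	G	het		4.0e-06		NFE:8.9e-06	deleterious	probably_damaging	D	D	H	D	27.5		P/LP	-
P04	SCN10A	CA	Novel	ENST00000449082.3	c.1200T>A	p.Tyr400Ter	stop_gained	HIGH	1	chr3	1200	T	A	het											38.0		-	-
P05	SCN10A	CA	Novel	ENST00000449082.3	c.4473C>G	p.Ile1491Met	missense_variant	MODERATE	1	chr3	4473	C	G	het					deleterious	possibly_damaging	D	D	M	D	23.4		-	-
P05	SCN10A	CA	Novel	ENST00000449082.3	c.4467C>G	p.Asn1489Lys	missense_variant	MODERATE	1	chr3	4467	C	G	het					deleterious	probably_damaging	D	D	M	D	24.8		-	-
P06	SCN10A	CA	Novel	ENST00000449082.3	c.4458C>G	p.Ile1486Met	missense_variant	MODERATE	1	chr3	4458	C	G	het					deleterious	possibly_damaging	D	D	M	D	22.9		-	-
P06	SCN10A	CA	Novel	ENST00000449082.3	c.4453C>A	p.Leu1485Ile	missense_variant	MODERATE	1	chr3	4453	C	A	het					deleterious	probably_damaging	D	A	M	D	23.1		-	-
P07	SCN10A	CA	rs770288343	ENST00000449082.3	c.5339C>T	p.Pro1780Leu	missense_variant	MODERATE	1	chr3	5339	C	T	het		8.0e-06		SAS:6.1e-05	deleterious	probably_damaging	D	D	M	D	28.7		-	-
P08	SCN5A	CA	rs199473124	ENST00000423572.7	c.1700T>A	p.Leu567Gln	missense_variant	MODERATE	1	chr3	1700	T	A	het		1.6e-05		NFE:2.8e-05	tolerated	benign	T	N	L	N	15.2		US	LP/P
P09	TRPM4	CA	rs754625848	ENST00000252826.10	c.247dup	p.Ala83GlyfsTer13	frameshift_variant	HIGH	1	chr19	247	G	GG	het		4.1e-06		AFR:2.5e-05								damaging	-	-
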