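gene	alleles	class	function	mitotic_flag
Apc5	apc5-CA-Paps	I	Cell cycle regulation	TRUE
Cdc27	cdc27-2	I	Cell cycle regulation	TRUE
Cdc28	cdc28-13	I	Cell cycle regulation	TRUE
Cdc20	cdc20-2,cdc20-3	I	Cell cycle regulation	TRUE
Bet2	bet2-1	I	Cell transport	FALSE
Sed5	sed5-1	I	Cell transport	FALSE
Sft1	sft1-15	I	Cell transport	FALSE
Abf1	abf1-102	I	Chromatin remodeling	FALSE
Rsc8	rsc8-ts16	I	Chromatin remodeling	FALSE
Swd2	swd2-1	I	Chromatin remodeling	FALSE
Tel2	tel2-15	I	Chromatin remodeling	FALSE
Ndc10	ndc10-1	I	Chromosome segregation	TRUE
Cdc14	cdc14-8	I	Chromosome segregation	TRUE
Cdc31	cdc31-2	I	Chromosome segregation	TRUE
Cse4	cse4-1	I	Chromosome segregation	TRUE
Dad2	dad2-9	I	Chromosome segregation	TRUE
Dam1	dam1-1,dam1-19	I	Chromosome segregation	TRUE
Duo1	duo1-2	I	Chromosome segregation	TRUE
Eco1	eco1-1	I	Chromosome segregation	TRUE
Esp1	esp1-1	I	Chromosome segregation	TRUE
Ipl1	ipl1-2	I	Chromosome segregation	TRUE
Mif2	mif2-3	I	Chromosome segregation	TRUE
Mps1	mps1-1	I	Chromosome segregation	TRUE
Mtw1	mtw1-ts	I	Chromosome segregation	TRUE
Nbp1	nbp1-1	I	Chromosome segregation	FALSE
Nnf1	nnf1-17,nnf1-48,nnf1-77	I	Chromosome segregation	TRUE
Nsl1	nsl1-5,nsl1-6	I	Chromosome segregation	TRUE
Nuf2	nuf2-61	I	Chromosome segregation	TRUE
Pds1	pds1-128	I	Chromosome segregation	TRUE
Sgt1	sgt1-3,sgt1-5	I	Chromosome segregation	FALSE
Sli15	sli15-3	I	Chromosome segregation	FALSE
Smc1	scm1-1	I	Chromosome segregation	TRUE
Smc3	scm3-42	I	Chromosome segregation	TRUE
Spc110	spc110-220	I	Chromosome segregation	TRUE
Spc24	spc24 4-2	I	Chromosome segregation	TRUE
Spc25	spc25-1	I	Chromosome segregation	TRUE
Spc29	spc29-20	I	Chromosome segregation	FALSE
Spc34	spc34 41-1	I	Chromosome segregation	TRUE
Stu1	stu1-12,stu1-5,stu1-6,stu1-7	I	Chromosome segregation	TRUE
Stu2	stu2-11,stu2-13	I	Chromosome segregation	TRUE
Dbf4	dbf4-2,dbf4-3,dbf4-ts	I	Chromosome segregation	TRUE
Smt3	smt3-42	I	Chromosome segregation	TRUE
Cdc6	cdc6-1	I	DNA replication	TRUE
Cdc7	cdc7-4	I	DNA replication	TRUE
Cdc21	cdc21-ts	I	DNA replication	FALSE
Psf1	psf1-1	I	DNA replication	FALSE
Kre5	kre5-ts2	I	Metabolism	FALSE
Krr1	krr1-18	I	Nucleolar and ribosome	FALSE
Nog2	nog2-1	I	Nucleolar and ribosome	FALSE
Nop2	nop2-5,nop2-9	I	Nucleolar and ribosome	FALSE
Nop7	nop7-1	I	Nucleolar and ribosome	FALSE
Rrp5	rrp5-delta6	I	Nucleolar and ribosome	FALSE
Arp3	arp3-G302Y	I	Polarity	FALSE
Cdc24	cdc24-5	I	Polarity	TRUE
Cdc43	cdc43-2	I	Polarity	FALSE
Exo70	exo70-20/37	I	Polarity	FALSE
Pan1	pan1-4	I	Polarity	TRUE
Sec23	sec23-1	I	Polarity	FALSE
Cdc34	cdc34-1	I	Protein degradation	TRUE
Met30	met30-6	I	Protein degradation	FALSE
Pre2	pre2-75	I	Protein degradation	FALSE
Rpt6	rpt6-20	I	Protein degradation	FALSE
Gpi13	gpi13-5	I	Protein modification	FALSE
Sec53	sec53-6	I	Protein modification	FALSE
Cdc39	cdc39-1	I	Transcription and RNA	FALSE
Hts1	hst1-1	I	Transcription and RNA	FALSE
Prp19	prp19-1	I	Transcription and RNA	FALSE
Prp2	prp2-1	I	Transcription and RNA	FALSE
Rse1	rse1-1	I	Transcription and RNA	FALSE
Slu7	slu7-ts2	I	Transcription and RNA	FALSE
Ssl2	ssl2-ts	I	Transcription and RNA	FALSE
Ssu72	ssu72-2	I	Transcription and RNA	FALSE
Yhc1	ych1-1	I	Transcription and RNA	FALSE
Pob3	pob3-7,pob3-L78R	II	Chromatin remodeling	FALSE
Spt16	spt16-1	II	Chromatin remodeling	FALSE
Crm1	crm1-1	III	Nuclear transport	FALSE
Rna1	rna1-1	III	Nuclear transport	FALSE
Srm1	srm1-ts	III	Nuclear transport	FALSE
Yrb1	yrb1-51	III	Nuclear transport	FALSE
Hym1	hym1-15	III	Polarity	FALSE
Mob2	mob2-14,mob2-19,mob2-22,mob2-28,mob2-36,mob2-38	III	Polarity	FALSE
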