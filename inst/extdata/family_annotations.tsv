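gene	chrom	pos	ref	alt	cdna_change	protein_change	functional_class	known_id	maf_ESP6500	maf_1000G	sift	polyphen_hvar	sanger_confirmed
SRA1	chr5	139936828	C	T	c.C91T	p.P31S	nonsynonymous_SNV	NA	NA	NA	0	1	TRUE
PHKG2	chr16	30767746	C	T	c.C706T	p.R236W	nonsynonymous_SNV	NA	NA	NA	0	1	TRUE
ZNF24	chr18	32919897	T	G	c.T464G	p.M155R	nonsynonymous_SNV	NA	NA	NA	0.02	0	TRUE
TMPRSS7	chr3	111797705	G	A	c.G1963A	p.G655S	nonsynonymous_SNV	NA	NA	NA	0	1	TRUE
ABLIM2	chr4	8055946	G	A	c.G791A	p.R264Q	nonsynonymous_SNV	NA	NA	NA	0.05	1	TRUE
FOXP1	chr3	71247489	C	T	c.C44T	p.A15V	nonsynonymous_SNV	NA	NA	NA	0.34	0.98	TRUE
GSTK1	chr7	142964824	G	A	c.G703A	p.G235R	nonsynonymous_SNV	NA	NA	NA	0.02	1	TRUE
LACRT	chr12	55028594	C	T	c.C32T	p.A11V	nonsynonymous_SNV	NA	NA	NA	0	0.99	TRUE
PAMR1	chr11	35456266	G	A	c.G1420A	p.G474R	nonsynonymous_SNV	NA	NA	NA	0	1	TRUE
TTN	chr2	179400887	G	A	c.G73392A	p.W24464X	stopgain	NA	NA	NA	NA	NA	TRUE
UEVLD	chr11	18553971	G	T	c.G1312T	p.V438L	nonsynonymous_SNV	rs143160739	5e-04	NA	0.37	0.96	TRUE
ITGA1	chr5	52240783	C	G	c.C3296G	p.S1099C	nonsynonymous_SNV	rs370052455	8e-04	NA	0.01	1	TRUE
BPTF	chr17	65850386	A	C	c.A944C	p.N315T	nonsynonymous_SNV	NA	NA	NA	0	1	TRUE
CACNB3	chr12	49220218	G	A	c.G688A	p.A230T	nonsynonymous_SNV	NA	NA	NA	0.01	1	TRUE
CUL4B	chrX	119680410	A	T	c.A838T	p.R280X	stopgain	NA	NA	NA	NA	NA	TRUE
SEMA3C	chr7	80374250	G	A	c.G2216A	p.R739Q	nonsynonymous_SNV	NA	NA	NA	0.01	0.99	TRUE
TBC1D22B	chr6	37280778	G	A	c.G1067A	p.S356N	nonsynonymous_SNV	NA	NA	NA	0.03	0.39	TRUE
CHCHD1	chr10	75541868	G	T	c.G35T	p.R12L	nonsynonymous_SNV	NA	NA	NA	0.01	0.99	TRUE
KCTD8	chr4	44177010	C	T	c.C1219T	p.R407C	nonsynonymous_SNV	NA	NA	NA	0	1	TRUE
CLCN4	chrX	10176455	G	A	c.G1214A	p.C405Y	nonsynonymous_SNV	NA	NA	NA	0	0.98	TRUE
LAT	chr16	29000901	G	T	c.G634T	p.A212S	nonsynonymous_SNV	NA	NA	NA	0.02	1	TRUE
ZNF304	chr19	57868409	A	T	c.A1172T	p.Y391F	nonsynonymous_SNV	NA	NA	NA	0.16	1	TRUE
ZNF674	chrX	46359537	C	A	c.C1487A	p.P496H	nonsynonymous_SNV	NA	NA	NA	0	1	TRUE
RAB3C	chr5	58147140	G	A	c.G646A	p.E216K	nonsynonymous_SNV	NA	NA	NA	0.01	0.99	TRUE
CASQ1	chr1	160165804	G	A	c.G769A	p.E257K	nonsynonymous_SNV	NA	NA	NA	0.01	0.99	TRUE
SYNBG1	chr1	1000000	A	G	NA	NA	nonsynonymous_SNV	rs900000001	0.24	0.25	0.8	0.1	NA
SYNBG2	chr2	2000000	C	T	NA	NA	nonsynonymous_SNV	NA	NA	NA	0.01	0.99	NA
SYNBG3	chr3	3000000	G	A	NA	NA	synonymous	NA	NA	NA	NA	NA	NA
SYNBG4	chr4	4000000	T	C	NA	NA	nonsynonymous_SNV	rs900000002	0.005	NA	0.01	0.99	NA
SYNBG5	chr5	5000000	A	T	NA	NA	nonsynonymous_SNV	NA	NA	NA	0.5	0.2	NA
SYNBG6	chr6	6000000	C	G	NA	NA	nonsynonymous_SNV	NA	NA	NA	0	1	NA
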