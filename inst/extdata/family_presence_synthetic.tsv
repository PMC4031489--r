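gene	chrom	pos	ref	alt	S1	S2	S3	S4	S5	S6	S7	S8	S9	S10
SRA1	chr5	139936828	C	T	1	1	0	1	1	1	1	1	0	0
PHKG2	chr16	30767746	C	T	1	1	0	1	0	1	1	0	0	0
ZNF24	chr18	32919897	T	G	1	0	0	1	1	1	0	0	0	0
TMPRSS7	chr3	111797705	G	A	1	1	0	0	1	1	0	0	0	0
ABLIM2	chr4	8055946	G	A	0	1	0	1	0	0	1	0	0	0
FOXP1	chr3	71247489	C	T	0	1	0	1	0	0	1	0	0	0
GSTK1	chr7	142964824	G	A	1	1	0	0	0	1	0	0	0	0
LACRT	chr12	55028594	C	T	1	0	0	1	1	0	0	0	0	0
PAMR1	chr11	35456266	G	A	1	1	0	0	1	0	0	0	0	0
TTN	chr2	179400887	G	A	0	1	0	1	0	0	1	0	0	0
UEVLD	chr11	18553971	G	T	1	1	0	0	0	0	0	0	0	0
ITGA1	chr5	52240783	C	G	1	1	0	0	0	0	0	0	0	0
BPTF	chr17	65850386	A	C	0	0	0	0	1	0	0	0	0	0
CACNB3	chr12	49220218	G	A	0	1	0	0	0	0	0	0	0	0
CUL4B	chrX	119680410	A	T	0	0	0	0	1	0	0	0	0	0
SEMA3C	chr7	80374250	G	A	0	0	0	0	1	0	0	0	0	0
TBC1D22B	chr6	37280778	G	A	0	0	0	0	1	0	0	0	0	0
CHCHD1	chr10	75541868	G	T	0	1	0	0	0	0	0	0	0	0
KCTD8	chr4	44177010	C	T	0	0	0	0	1	0	0	0	0	0
CLCN4	chrX	10176455	G	A	0	0	0	0	1	0	0	0	0	0
LAT	chr16	29000901	G	T	0	0	0	0	1	0	0	0	0	0
ZNF304	chr19	57868409	A	T	0	0	0	0	1	0	0	0	0	0
ZNF674	chrX	46359537	C	A	0	0	0	0	1	0	0	0	0	0
SYNBG1	chr1	1000000	A	G	1	1	1	1	1	1	1	1	0	0
SYNBG2	chr2	2000000	C	T	1	0	1	0	0	0	0	0	0	0
SYNBG3	chr3	3000000	G	A	0	1	0	1	0	0	0	0	0	0
SYNBG4	chr4	4000000	T	C	0	1	0	0	0	0	0	0	0	0
SYNBG5	chr5	5000000	A	T	0	0	0	1	0	0	0	0	0	0
SYNBG6	chr6	6000000	C	G	0	0	0	0	1	0	0	0	1	0
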