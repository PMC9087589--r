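arm	region	snv_id	gene	cytoband	genotype	ref	alt	aa_change	af_chinese	af_east_asian	impact	tf_mirna	samples
regions	exon	rs17244632	COBLL1	2q24.3	homo_inherit	G	A	p.T833I	0.044851	0.0327	possibly_damaging	NA	75
regions	exon	rs13362036	CCNJL	5q33.3	homo_inherit	G	A	p.H186Y	0.164452	0.1627	possibly_damaging	NA	6/100
regions	exon	rs10764749	MKI67	10q26.2	homo_inherit	C	T	p.R2426Q	0.104651	0.1181	probably_damaging	NA	100
regions	exon	rs2071496	MKI67	10q26.2	homo_inherit	G	C	p.T2508S	0.104651	0.119	probably_damaging	NA	100
regions	exon	rs2152143	MKI67	10q26.2	homo_inherit	C	T	p.G682S	0.104651	0.1181	probably_damaging	NA	100
regions	exon	rs3740423	MKI67	10q26.2	homo_inherit	T	A	p.E1043V	0.104651	0.1181	probably_damaging	NA	100
regions	exon	rs7938342	LSP1	11p15.5	homo_inherit	T	A	p.H34Q	0.767442	0.7688	possibly_damaging	NA	86
regions	exon	rs17301182	DYNC2H1	11q22.3	homo_inherit	C	T	p.H341Y	0.086379	0.0933	possibly_damaging	NA	5
regions	exon	rs688906	DYNC2H1	11q22.3	homo_inherit	A	G	p.K1413R	0.782392	0.7827	possibly_damaging	NA	71/79
regions	exon	rs2302686	LRP6	12p13.2	hetero_gain	G	C	p.S817C	0.009967	0.0109	probably_damaging	NA	5
regions	exon	rs2041290	AKAP3	12p13.32	hetero_gain	A	G	p.S700L	0.126246	0.1647	probably_damaging	NA	65
regions	exon	rs2041291	AKAP3	12p13.32	hetero_gain	G	A	NA	0.126246	0.1647	probably_damaging	NA	65
regions	exon	rs12227879	PARPBP	12q23.2	homo_inherit	G	A	p.V319M	0.033223	0.0327	probably_damaging	NA	42
regions	exon	rs144896967	NPIPA5	16p13.11	hetero_gain	C	T	p.E268K	0.023256	0.0268	possibly_damaging	NA	12
regions	exon	rs62038492	NOMO1	16p13.11	hetero_gain	A	G	p.E1153G	NA	NA	possibly_damaging	NA	74
regions	exon	rs10508	HCFC1R1	16p13.3	homo_inherit	G	T	p.P73Q	0.109635	0.1181	possibly_damaging	NA	98
regions	exon	rs45459806	PDIA2	16p13.3	homo_inherit	C	T	p.A316V	0.018272	0.0198	possibly_damaging	NA	100
regions	exon	rs45478794	PKD1	16p13.3	homo_inherit	G	A	p.T3509M	0.068106	0.0625	possibly_damaging	NA	2
regions	exon	rs45529833	PDIA2	16p13.3	homo_inherit	C	G	p.P382A	0.021595	0.0218	probably_damaging	NA	100
regions	exon	rs61734410	CACNA1H	16p13.3	homo_inherit	C	T	p.P640L	0.835548	0.8383	possibly_damaging	NA	99/100
regions	exon	rs9806942	RGS11	16p13.3	homo_inherit	C	T	p.V167M	0.325581	0.3185	probably_damaging	NA	100
regions	exon	rs11649804	RAI1	17p11.2	homo_inherit	C	A	p.P165T	0.845515	0.8353	probably_damaging	NA	100
regions	exon	rs2272962	BCAS4	20q13.13	homo_inherit	G	T	p.E56D	0.131229	0.1329	probably_damaging	NA	75
regions	promoter	rs67529412	ZNF598	16p13.3	homo_gain	C	G	NA	NA	NA	NA	ELK1_01	8
regions	promoter	rs866882393	WFS1	4p16.1	hetero_gain	G	C	NA	NA	NA	NA	PAX5_01	42/65/78
regions	utr3	rs117345841	ULK2	17p11.2	hetero_gain	T	C	NA	0.064784	0.0665	NA	miR-130/301	65
geneset	exon	rs680277	RGS8	1q25.3	homo_inherit	T	C	p.N3S	0.146179	0.1399	benign	NA	99
geneset	exon	rs61732315	PPFIA4	1q32.1	homo_inherit	G	T	p.A825S	0.171096	0.1577	possibly_damaging	NA	75
geneset	exon	rs2229848	LAMA2	6q22.33	homo_inherit	C	T	p.A2583V	0.621262	0.6369	probably_damaging	NA	5/43/88
geneset	exon	rs2244008	LAMA2	6q22.33	homo_inherit	A	G	p.T2632A	0.124585	0.1319	benign	NA	6/65
geneset	exon	rs2644275	GNA12	7p22.2	homo_inherit	G	A	p.T23I	0.222591	0.2321	benign	NA	43
geneset	exon	rs798488	GNA12	7p22.2	homo_inherit	T	C	p.M1V	0.219269	0.2232	NA	NA	43
geneset	exon	NA	ADCY6	12q13.12	hetero_gain	G	A	p.L329F	NA	NA	probably_damaging	NA	8
geneset	exon	rs2301868	TSPOAP1	17q22	homo_inherit	C	T	p.G1770E	0.144518	0.1161	probably_damaging	NA	79
geneset	exon	rs1050457	PALM	19p13.3	homo_gain	A	G	p.T107A	0.534884	0.5446	benign	NA	99
geneset	exon	rs143873938	FLNA	Xq28	homo_gain	C	T	p.V528M	0.047826	0.0419	probably_damaging	NA	5/65/69
geneset	exon	rs781798819	FLNA	Xq28	homo_gain	T	C	p.K676R	0.006522	0.0065	benign	NA	78
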