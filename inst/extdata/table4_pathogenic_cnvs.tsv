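sample_id	sex	locus	chrom	start	end	size_kb_printed	type	origin	genes	control_carriers
U-728	male	1q31.1	1	189384373	190699301	1315	deletion	unknown	BRINP3, KINC01351, LOC440704	0
U-1340	male	2p13.1-12	2	74857355	75324605	467	duplication	maternal	MIAP, SEMA4F, HK2, LINC01291, POLE4, TACR1, MIR5000	0
U-866	male	2p16.1	2	58164223	59360403	1196	duplication	paternal	VRK2, FANCL, LINC01122	0
U-985	male	2q14.3	2	125532806	126965458	1433	duplication	maternal	CNTNAP5	0
U-2170	male	2q14.3-21.1	2	129497534	131211699	1714	deletion	maternal	LOC101927881 to CYP4F62P (18 genes)	0
U-1726	female	2q37.3	2	238318241	243089444	4771	deletion	de_novo	COL6A3 to LOC728323 (77 genes)	0
U-925	male	3p24.3	3	19283615	19844654	561	duplication	paternal	KCNH8, MIR4791	0
U-480	male	4p13	4	44009201	44586716	578	duplication	paternal	LVCAT1, KCTD8	0
U-2075	male	4q12-13.1	4	58189742	62734625	4545	duplication	maternal	LOC101928851 to ADGRL3 (6 genes)	0
U-1535	male	4q31.22	4	146812877	148129943	1317	deletion	de_novo	ZNF827 to TTC29 (8 genes)	0
U-1385	male	5p12-11	5	45288787	46334867	1046	duplication	paternal	HCN1	0
U-2058	male	5p15.33	5	1685594	2197203	512	duplication	de_novo	MIR4277 to CTD-2194D22.4 (6 genes)	1
U-215	male	5q13.2	5	68867282	70391241	1524	duplication	paternal	GTF2H2C to LOC647859 (14 genes)	0
U-2075	male	5q32	5	144772150	146559069	1787	deletion	paternal	PRELID2 to PPP2R2B-IT1 (11 genes)	0
U-1428	female	7p14.1	7	39137061	39545773	409	duplication	paternal	POU6F2, POU6F2-AS1	0
U-754	male	7p22.3	7	1203841	1638496	435	duplication	paternal	LOC101927021 to PSMG3-AS1 (8 genes)	0
U-890	male	7q22.3	7	104676522	105099343	423	duplication	paternal	KMT2E, SRPK2, PUS7	0
U-717	male	7q31.31	7	119313222	120243311	930	duplication	maternal	LVCAT5, KCND2	0
U-2829	male	7q32.1	7	127266882	127670004	403	duplication	maternal	SND1, SND1-IT1, LRRC4	0
U-1753	male	8p22	8	13277834	13841792	564	deletion	paternal	DLC1, C8orf48, LOC102725080	0
U-1130	male	8p23.2	8	2179516	3890012	1710	duplication	maternal	LOC101927815, CSMD1	0
U-1414	male	8p23.3	8	562629	1159817	597	duplication	maternal	ERICH1, ERICH1-AS1, LOC401442	0
U-1753	male	8q21.11	8	75793077	76234219	441	duplication	maternal	CRISPLD1, CASC9	0
U-363	male	8q24.23	8	136620080	138711817	2092	deletion	paternal	KHDRBS3, LOC101927915	0
U-1511	male	9p21.3	9	22190562	22988892	798	duplication	paternal	DMRTA1, LINC01239	0
U-1269	male	9q32	9	116314918	117370538	1056	deletion	de_novo	RGS3 to ATP6V1G1 (11 genes)	0
U-1414	male	9q33.2-33.3	9	125422424	125947085	525	duplication	de_novo	OR1L1 to STRBP (16 genes)	0
U-1924	male	10p11.21	10	34670528	35328422	658	duplication	paternal	PARD3, PARD3-AS1, CUL2	0
U-1255	male	10q26.2	10	128138653	128597833	459	duplication	maternal	C10orf90, DOCK1	0
U-1230	male	12p11.1	12	33752330	34532722	780	duplication	paternal	ALG10	1
U-1691	male	12p11.1	12	33752330	34532722	780	duplication	paternal	ALG10	1
U-1967	male	12q24.33	12	130579093	131130277	551	duplication	maternal	FZD10-AS1, FZD10, PIWIL1, RIMBP2	0
U-1850	male	15q13.3	15	33145711	33546098	400	duplication	maternal	FMN1, TMCO5B	0
U-2015	male	16p13.3	16	5942659	7000800	1058	duplication	maternal	RBFOX1	0
U-1578	male	17p13.3	17	833790	1516480	683	deletion	de_novo	NXN to SLC43A2 (13 genes)	0
U-212	male	17p13.3	17	172683	577890	405	duplication	paternal	RPH3AL to VPS53 (6 genes)	2
U-1999	male	17q25.3	17	78951153	79505624	554	duplication	de_novo	CHMP6 to FSCN2 (22 genes)	0
U-1999	male	17q25.3	17	79619226	80178991	560	duplication	de_novo	PDE6G to CCDC57 (34 genes)	0
U-1255	male	18p11.31-11.23	18	7079985	7563165	483	duplication	paternal	LAMA1, LRRC30	5
U-1519	male	18p11.32	18	543161	2240220	1697	duplication	maternal	CETN1 to LINC00470 (8 genes)	0
U-1957	male	19q13.42-13.43	19	55237234	59097842	3860	duplication	de_novo	KIR3DL3 to CENPBD1P1 (160 genes)	0
U-2131	male	20q13.32-13.33	20	58022339	59007873	986	duplication	paternal	PHACTR3 to MIR646 (11 genes)	0
U-1452	male	22q11.1	22	16055171	17330096	1275	duplication	maternal	DUXAP8 to HSFY1P1 (14 genes)	0
U-2200	male	Xp22.31	X	6467902	8135645	1668	deletion	unknown	PUDP to MIR651 (7 genes)	0
U-1626	male	Xp22.31	X	6659217	7975015	1316	deletion	unknown	PUDP to PNPLA4 (6 genes)	0
U-273	male	Xq12-13.1	X	67443166	67900951	458	duplication	unknown	OPHN1, YIPF6, STARD8	0
U-1160	male	Xp11.21-11.1	X	57384047	58438177	1054	duplication	unknown	PAAH2, ZXD8, NLRP2B, ZXDA	0
U-728	male	Xq21.33	X	96705629	98004847	1299	duplication	unknown	DIAPH2, DIAPH2-AS1	0
U-919	male	Xp22.31	X	6455151	8145721	1691	duplication	unknown	PUDP to VCX2 (7 genes)	0
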