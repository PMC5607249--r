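sample_id	sex	locus	chrom	start	end	size_kb_printed	type	genes	control_carriers
U-1902	male	7q31.2	7	116365096	116443274	78	duplication	MET	0
U-1638	male	7q35	7	145064742	145950454	886	duplication	CNTNAP2	0
U-1067	male	15q11.2-13.1	15	24782255	28709280	3927	duplication	PWRN1 to MIR4509 (144 genes)	1
U-1807	male	15q11.2	15	23641502	28560804	4919	duplication	GOLGA6L2 to HERC2 (148 genes)	1
U-2158	male	15q13.3	15	32458661	32857470	399	deletion	CHRNA7	6
U-2233	male	16p11.2	16	29591757	30191895	600	duplication	SMG1P2 to MAPK3 (29 genes)	0
U-1199	male	22q11.21-11.22	22	21917141	22970127	1053	deletion	UBE2L3 to LL22NC03-63E9.3 (14 genes)	0
U-1994	male	22q11.21	22	18781534	19006984	225	duplication	LOC102725072 to DGCR9 (6 genes)	9
U-801	male	22q11.21	22	18640300	21611337	2971	duplication	USP18 to FAM230B (83 genes)	0
U-830	male	22q11.21	22	19024794	21611337	2587	deletion	DGCR2 to FAM230B (70 genes)	0
U-1459	male	22q13.33	22	51127905	51234443	107	deletion	SHANK3, ACR, RABL2B, RPL23AP82	0
U-1957	male	22q13.33	22	51087264	51234443	147	deletion	SHANK3, ACR, RABL2B, RPL23AP82	0
U-2239	male	22q13.32-q13.33	22	49388701	51188494	1800	duplication	C22orf34 to ACR (40 genes)	0
U-1344	male	Xp22.3	X	5940647	6666470	726	duplication	NLGN4X	0
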