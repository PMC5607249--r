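sample_id	locus	chrom	start	end	size_kb_printed	type	genes	control_carriers
U-2075	5q32	5	144772150	146559069	1787	deletion	PRELID2, GRXCR2, SH3RF2, PLAC8L1, LARS, RBM27, POU4F3, TCERG1, PPP2R2B	0
U-2075	4q12-13.1	4	58189742	62734625	4545	duplication	LPHN3	0
U-1753	8p22	8	13277834	13841792	564	deletion	DLC1	0
U-1753	8q21.11	8	75793077	76234219	441	duplication	CRISPLD1	0
U-1255	18p11.31-p11.23	18	7079985	7563165	483	duplication	LAMA1	5
U-1255	10q26.2	10	128138653	128597833	459	duplication	C10orf90, DOCK1	0
U-1414	9q33.2-q33.3	9	125422424	125947085	525	duplication	OR1L1, OR1L3, OR1L4, OR1L6, OR5C1, OR1K1, PDCL, RC3H2, ZBTB6, ZBTB26, RABGAP1, GPR21, NCRNA00287, MIR600, STRBP	0
U-1414	8p23.3	8	562629	1159817	597	duplication	ERICH1	0
U-1999	17q25.3	17	78951153	79505624	554	duplication	CHMP6 to FSCN2 (13 genes listed)	0
U-1999	17q25.3	17	79619226	80178991	560	duplication	PDE6G to CCDC57 (29 genes listed)	0
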