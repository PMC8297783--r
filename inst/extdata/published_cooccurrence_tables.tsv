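table_id	label_a	label_b	neither	a_only	b_only	both	printed_log2_or	printed_p
rtk_ligand	AXL	GAS6	358	16	23	7	2.768	<0.001
rtk_ligand	CSF1R	CSF1	355	21	17	11	>3	<0.001
rtk_ligand	DDR2	COL4A1	310	62	21	11	1.389	0.016
rtk_ligand	DDR2	COL10A1	309	70	15	10	1.557	0.013
rtk_ligand	KDR	VEGFA	340	30	27	7	1.555	0.026
rtk_ligand	MST1R	MST1	364	17	14	9	>3	<0.001
rtk_ligand	PDGFRA	PDGFA	347	30	21	6	1.725	0.024
rtk_ligand	TEK	ANGPT2	364	22	13	5	2.670	0.004
emt_ta	ZEB1	ZEB2	363	16	13	12	>3	<0.001
emt_ta	MYC	SNAI2	337	35	17	15	>3	<0.001
emt_ta	TWIST1	TWIST2	371	29	1	3	>3	0.002
emt_ta	RUNX2	ZEB1	366	10	23	5	2.992	0.002
emt_ta	SNAI1	TWIST1	357	15	26	6	2.457	0.004
emt_ta	TWIST1	ZEB2	353	26	19	6	2.1	0.009
emt_ta	RUNX2	ZEB2	368	11	21	4	2.672	0.010
emt_ta	SNAI1	TWIST2	381	19	2	2	>3	0.015
emt_ta	TWIST2	ZEB2	377	2	23	2	>3	0.020
emt_ta	SOX9	TWIST1	346	26	26	6	1.619	0.031
group1_emt	MYC	MET	336	43	16	9	2.136	0.002
group1_emt	MYC	LYN	333	42	19	10	2.061	0.002
group1_emt	RUNX2	AXL	366	15	19	4	2.361	0.018
group1_emt	RUNX2	FGFR1	342	13	43	6	1.876	0.018
group1_emt	RUNX2	FYN	365	15	20	4	2.283	0.02
group1_emt	SNAI1	TIE1	346	17	33	8	2.303	0.002
group1_emt	SNAI1	FGFR1	333	22	35	14	2.598	<0.001
group1_emt	SNAI1	ABL2	337	29	31	7	1.392	0.04
group1_emt	SNAI1	LYN	350	25	18	11	>3	<0.001
group1_emt	SOX2	EPHB3	351	12	25	16	>3	<0.001
group1_emt	SOX2	FYN	350	30	19	5	1.618	0.046
group1_emt	SOX2	PTK7	357	31	12	4	1.941	0.041
group1_emt	TWIST1	ABL1	353	24	19	8	2.631	<0.001
group1_emt	TWIST1	DDR2	305	19	67	13	1.639	0.004
group1_emt	TWIST1	PDGFRA	347	21	25	11	2.862	<0.001
group1_emt	TWIST1	PDGFRB	353	25	19	7	2.379	0.002
group1_emt	TWIST1	TIE1	339	24	33	8	1.776	0.009
group1_emt	TWIST1	TEK	351	26	21	6	1.948	0.014
group1_emt	TWIST1	ROR2	350	26	22	6	1.876	0.016
group1_emt	TWIST2	FYN	379	1	21	3	>3	<0.001
group1_emt	TWIST2	ABL1	375	2	25	2	>3	0.024
group1_emt	TWIST2	PDGFRA	366	2	34	2	>3	0.041
group1_emt	TWIST2	PDGFRB	376	2	24	2	>3	0.022
group1_emt	TWIST2	TEK	375	2	25	2	>3	0.024
group1_emt	ZEB1	ABL1	348	29	15	12	>3	<0.001
group1_emt	ZEB1	DDR2	301	23	62	18	1.926	<0.001
group1_emt	ZEB1	CSFR1	341	31	22	10	2.322	<0.001
group1_emt	ZEB1	AXL	347	34	16	7	2.159	0.005
group1_emt	ZEB1	FYN	346	34	17	7	2.067	0.006
group1_emt	ZEB1	ITK	344	35	19	6	1.634	0.031
group1_emt	ZEB1	FGFR1	323	32	40	9	1.183	0.044
group1_emt	ZEB1	ROR1	348	30	15	11	>3	<0.001
group1_emt	ZEB1	TEK	347	30	16	11	2.991	<0.001
group1_emt	ZEB1	TIE1	335	28	28	13	2.474	<0.001
group1_emt	ZEB1	PDGFRA	339	29	24	12	2.547	<0.001
group1_emt	ZEB1	PTK7	354	34	9	7	>3	<0.001
group1_emt	ZEB1	PDGFRB	345	33	18	8	2.216	0.002
group1_emt	ZEB1	ROR2	343	33	20	8	2.056	0.004
group2_emt	MYC	PTK2	333	33	19	19	>3	<0.001
group2_emt	MYC	TXK	340	44	12	8	2.365	0.002
group2_emt	SNAI1	PTK2	341	25	27	11	2.474	<0.001
group2_emt	SNAI1	TYK2	356	20	23	5	1.952	0.022
group2_emt	SNAI2	PTK2	341	25	27	11	2.474	<0.001
group2_emt	SOX2	TNK2	352	14	24	14	>3	<0.001
group2_emt	SOX2	TYK2	353	23	23	5	1.738	0.035
group2_emt	ZEB1	DDR1	344	35	19	6	1.634	0.031
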