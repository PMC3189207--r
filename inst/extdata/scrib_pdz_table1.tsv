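# Scrib PDZ-1/2/3 domain-ligand interaction panel: 56 candidate ligands from the
# human proteome, C-terminal 10-mers, measured binding affinities (Kd, uM; NB =
# no binding detected), per-domain prediction scores and Z scores standardized
# against the human protein database. in_vivo = 1 marks proteins previously
# reported to interact with Scrib in vivo via its PDZ domains.
index	protein	gene_id	cterm	kd_pdz1	kd_pdz2	kd_pdz3	score_pdz1	score_pdz2	score_pdz3	z_pdz1	z_pdz2	z_pdz3	in_vivo
1	ABR	NM_001092.3	RNTLYFSTDV	12.5	10.4	2.9	-0.09	0.3	-0.01	2.3	3.4	2.3	0
2	ACBD6	NM_032360.1	VLQRHTTGKA	NB	NB	NB	-1.39	-1.36	-2.6	-1.2	-1.2	-1.7	0
3	AHDC1	BC002677.1	PEDTFTVTSL	19.2	NB	10.4	0.43	0.32	0.31	3.7	3.4	2.8	0
4	ANKS4B	NM_145865.1	QPGQLVDTSL	NB	NB	28.2	0.58	0.43	0.31	4.1	3.7	2.8	0
5	APC	NP_000029	HSGSYLVTSV	12.3	9.5	6.7	0.31	0.27	0.8	3.4	3.3	3.6	1
6	ARD50	BC024725.1	SFNYKKETPL	23.6	34.3	1.5	0.83	0.71	1.2	4.7	4.5	4.2	0
7	ARHGEF16	NM_014448.2	MERLRVETDV	27.5	7.7	2.1	0.75	1	1	4.5	5.3	3.9	0
8	BEGAIN	NM_020836.2	KAQLYGTLLN	NB	NB	NB	-1.91	-1.94	-2.2	-2.6	-2.8	-1.1	0
9	b-PIX	NP_003890	NDPAWDETNL	5.3	16.8	4.9	1	0.97	1	5.2	5.2	3.9	0
10	C11orf52	NM_080659.1	RYDSKNGTLV	NB	NB	26.5	-0.31	-0.07	0.16	1.7	2.4	2.6	0
11	C19orf57	BC012945.1	PRGDPPWREL	NB	NB	NB	-0.67	-0.69	-1.02	0.7	0.6	0.7	0
12	DIRAS1	NM_145173.1	DRVKGKCTLM	NB	NB	NB	-0.3	-0.24	-0.44	1.7	1.9	1.7	0
13	DSC54	NM_016644.1	ILRKSTTTTV	NB	NB	40.1	-0.21	0	-0.52	2	2.5	1.5	0
14	EPHA2	PV3688	DQVNTVGIPI	NB	NB	NB	-0.87	-0.84	-1.46	0.2	0.2	0	0
15	EPHA3	PV3359	TQSKNGPVPV	129	NB	NB	-1.04	-0.89	-1.11	-0.3	0.1	0.6	0
16	EPHA5	PV3840	VQLVNGMVPL	NB	75.7	45.6	-0.8	-0.84	-1.04	0.4	0.2	0.7	0
17	EPHA7	PV3689	LHLHGTGIQV	NB	NB	NB	-0.78	-0.58	-1.53	0.4	0.9	-0.1	0
18	EPHA8	PV3844	DPELEALHCL	NB	24.9	38.8	-0.73	-0.75	-1.19	0.6	0.5	0.5	0
19	FAM105B	NM_138348.3	PVRVCEETSL	1.9	17.6	3.4	0.88	0.66	1.24	4.9	4.4	4.3	0
20	FAM126B	NM_173822.1	SFNMQLISQV	NB	NB	39.3	-0.73	-0.73	-0.42	0.6	0.5	1.7	0
21	FLT1	NM_002019.1	SVVLYSTPPI	NB	NB	NB	-1.25	-1.24	-1.76	-0.8	-0.9	-0.4	0
22	FOXl1	NM_144769.1	VLYPREGTEV	NB	24.7	11.7	-0.19	0.07	0.31	2	2.7	2.8	0
23	GLO1	BC001741.1	LNPNKMATLM	NB	NB	59.5	-0.45	-0.38	-0.36	1.3	1.5	1.8	0
24	KCNA6	NM_002235.2	YAEKRMLTEV	NB	NB	34.8	-0.02	0.21	0.51	2.5	3.1	3.1	0
25	KCNJ10	BC034036.1	SALSVRISNV	NB	NB	13.2	-0.56	-0.37	-0.04	1	1.5	2.3	0
26	KIRREL2	BC007312.1	PSHPRLQTHV	NB	NB	21.3	0.33	0.36	0.08	3.4	3.5	2.5	0
27	LIMD1	NM_014240.1	SSTALHQHHF	NB	NB	NB	-0.68	-0.68	-1.92	0.7	0.7	-0.7	0
28	LPP	NP_005569	VLTAKASTDL	24.2	NB	11.3	0.02	0.2	-0.13	2.6	3.1	2.1	1
29	MAPK12	PV3654	GARVSKETPL	20.3	56.1	1.7	0.83	0.71	1.2	4.7	4.5	4.2	0
30	MCM7	BC009398.1	NASRTRITFV	NB	NB	24.1	-0.07	0.13	0.41	2.3	2.9	3	0
31	MPG	BC014991.1	DRVAEQDTQA	NB	NB	186	-0.31	-0.22	-0.76	1.7	1.9	1.1	0
32	MTERFD1	NM_015942.3	QDFEKFLKTL	NB	NB	NB	-0.65	-0.71	-1.39	0.8	0.6	0.2	0
33	MUSK	PV3834	CERAEGTVSV	NB	NB	143	-0.75	-0.74	-1.01	0.5	0.5	0.8	0
34	PACAP	BC021275.1	EKVSATREEL	NB	NB	88.1	-1.01	-0.84	-1.4	-0.2	0.2	0.1	0
35	PDGFRA	NM_002609	PRAEAEDSFL	NB	NB	52.0	-0.84	-0.84	-0.32	0.3	0.2	1.8	0
36	PDGFRB	NM_002609	PRAEAEDSFL	NB	NB	59.6	-0.84	-0.84	-0.32	0.3	0.2	1.8	0
37	PRKCA	P2227	FVHPILQSAV	17.4	46.0	9.8	-0.51	-0.49	-0.14	1.2	1.2	2.1	0
38	PRKCB1	P2281	YTNPEFVINV	NB	NB	NB	-0.57	-0.34	-0.71	1	1.6	1.2	0
39	PSMA8	BC042820.1	AEKKKSKKSV	NB	NB	177	-0.43	-0.41	-1.35	1.4	1.4	0.2	0
40	PTE1	NM_005469.2	VKPQVSESKL	NB	NB	NB	-0.28	-0.44	0.28	1.8	1.3	2.8	0
41	RASL11B	NM_023940.1	SAKVRTVTSV	NB	NB	30.0	0.32	0.43	0.36	3.4	3.7	2.9	0
42	RPS6KA1	NM_001006665	RVRKLPSTTL	NB	NB	27.0	-0.06	-0.05	-0.39	2.4	2.4	1.7	0
43	RPS6KA2	NM_001006932	GMKRLTSTRL	NB	62.7	25.2	-0.02	-0.01	-0.31	2.5	2.5	1.9	0
44	SRC	NM_005417.3	EPQYQPGENL	NB	NB	48.6	-0.77	-0.74	-1.55	0.5	0.5	-0.1	0
45	STK16	BC053998.1	PAPGQHTTQI	NB	NB	52.2	-0.45	-0.38	-0.49	1.3	1.5	1.6	0
46	STK29	BC024291.1	KVATSYESSL	NB	NB	3.2	0.29	0.01	0.59	3.3	2.6	3.3	0
47	SYNJ2BP	BC007704.1	WAFMRYRQQL	NB	NB	32.0	-0.81	-0.68	-1.82	0.4	0.7	-0.5	0
48	TANK	NM_133484.1	VDIASAESSI	102	NB	13.6	-0.08	-0.29	0.49	2.3	1.7	3.1	0
49	TBK1	PV3504	DGGLRNVDCL	77	NB	67.8	-0.76	-0.75	-0.49	0.5	0.5	1.6	0
50	TPM2	NM_003289.3	DNALNDITSL	NB	NB	54.4	0.6	0.48	0.25	4.1	3.9	2.7	0
51	TRIM21	NM_003141.2	NIGSQGSTDY	NB	NB	116	-0.68	-0.43	-0.74	0.7	1.4	1.2	0
52	UBXD1	NM_025241.1	ELLSAIEKLL	NB	NB	NB	-0.03	-0.22	-0.38	2.4	1.9	1.7	0
53	VANGL2	NP_065068	VMRLQSETSV	21.6	8.7	8.8	0.86	0.83	1.25	4.8	4.8	4.3	1
54	ZADH2	NM_175907.3	ELPHSVNSKL	NB	NB	NB	-0.63	-0.69	-0.99	0.8	0.6	0.8	0
55	ZNF654	NM_018293.1	SSAQPSETIL	NB	32.1	18.3	0.6	0.48	0.91	4.1	3.9	3.8	0
56	ZO2	NP_004808	QSARYDTEL	16.0	NB	13.7	0.06	0.08	0.2	2.7	2.8	2.6	1
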