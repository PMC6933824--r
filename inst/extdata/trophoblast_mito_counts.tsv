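protein_id	gene	protein_name	avg_unique_peptides_cyto	avg_unique_peptides_syncytio	ratio_printed	log2fc_printed
P06576	ATP5B	ATP synthase subunit beta, mitochondrial	232	136	1.70073	0.766154
P25705	ATP5A1	ATP synthase subunit alpha, mitochondrial	82	54	1.509091	0.59368
P31040	SDHA	Succinate dehydrogenase [ubiquinone] flavoprotein subunit, mitochondrial	41	25	1.615385	0.691878
Q9UI09	NDUFA12	NADH dehydrogenase [ubiquinone] 1 alpha subcomplex subunit 12	12	4	2.6	1.378512
Q16822	PCK2	Phosphoenolpyruvate carboxykinase [GTP], mitochondrial	7	0	8	3
P11498	PC	Pyruvate carboxylase, mitochondrial	40	17	2.277778	1.187627
Q8NCN5	PDPR	Pyruvate dehydrogenase phosphatase regulatory subunit, mitochondrial	20	9	2.1	1.070389
P42704	LRPPRC	Leucine-rich PPR motif-containing protein, mitochondrial	71	38	1.846154	0.884523
P49748	ACADVL	Very long-chain specific acyl-CoA dehydrogenase, mitochondrial	101	69	1.457143	0.543142
P12694	BCKDHA	2-oxoisovalerate dehydrogenase subunit alpha, mitochondrial	14	5	2.5	1.321928
O15382	BCAT2	Branched-chain-amino-acid aminotransferase, mitochondrial	28	15	1.8125	0.857981
P09622	DLD	Dihydrolipoyl dehydrogenase, mitochondrial	55	34	1.6	0.678072
P23378	GLDC	Glycine dehydrogenase (decarboxylating), mitochondrial	22	8	2.555556	1.353637
P12236	SLC25A6	ADP/ATP translocase 3	38	18	2.052632	1.037475
Q02978	SLC25A11	Mitochondrial 2-oxoglutarate/malate carrier protein	38	18	2.052632	1.037475
P21397	MAOA	Amine oxidase [flavin-containing] A	263	180	1.458564	0.544548
P30038	ALDH4A1	Delta-1-pyrroline-5-carboxylate dehydrogenase, mitochondrial	47	29	1.6	0.678072
P10809	HSPD1	60 kDa heat shock protein, mitochondrial	209	139	1.5	0.584963
P38646	HSPA9	Stress-70 protein, mitochondrial	75	50	1.490196	0.575502
Q12931	TRAP1	Heat shock protein 75 kDa, mitochondrial	23	11	2	1
P21796	VDAC1	Voltage-dependent anion-selective channel protein 1	126	85	1.476744	0.56242
P45880	VDAC2	Voltage-dependent anion-selective channel protein 2	78	52	1.490566	0.57586
P04179	SOD2	Superoxide dismutase [Mn], mitochondrial	27	11	2.333333	1.222392
P35232	PHB	Prohibitin	74	52	1.415094	0.500898
P11021	HSPA5	78 kDa glucose-regulated protein	93	129	0.723077	-0.46778
P14625	HSP90B1	Endoplasmin	94	147	0.641892	-0.6396
P07237	P4HB	Protein disulfide-isomerase	47	64	0.738462	-0.43741
P51659	HSD17B4	Peroxisomal multifunctional enzyme type 2	26	40	0.658537	-0.60266
Q9NX63	CHCHD3	MICOS complex subunit MIC19	10	22	0.478261	-1.06413
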