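symbol	synonyms
ATP5B	ATP5F1B,ATPSB
ATP5A1	ATP5F1A,ATP5A
SDHA	FP,SDHF
NDUFA12	B17.2,DAP13
PCK2	PEPCK2,PEPCK-M
PC	PCB
PDPR	KIAA1990
LRPPRC	LRP130,GP130
ACADVL	VLCAD,ACAD6
BCKDHA	MSUD1,BCKDE1A
BCAT2	BCATM,BCT2
DLD	LAD,DLDH,GCSL
GLDC	GCSP
SLC25A6	ANT3
SLC25A11	OGC,SLC20A4
MAOA	
ALDH4A1	P5CDH,ALDH4
HSPD1	HSP60,GROEL
HSPA9	GRP75,MORTALIN,MOT
TRAP1	HSP75,HSP90L
VDAC1	PORIN,VDAC
VDAC2	POR
SOD2	MNSOD,IPOB
PHB	PHB1
HSPA5	GRP78,BIP
HSP90B1	GRP94,TRA1
P4HB	PDI,PDIA1
HSD17B4	MFE2,DBP
CHCHD3	MIC19,MINOS3
CS	
TFAM	TCF6
NDUFS1	
MFN1	
MFN2	
PDHA1	PHE1A
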