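gene	tpm_cyt	tpm_syn	ratio_printed	log2fc_printed
ATP5B	389.168	96.36427	4.007301263	2.002631
ATP5A1	242.5827	219.799	1.103187599	0.141678
SDHA	25.28696	16.19172	1.529047892	0.612634
NDUFA12	130.6539	71.19643	1.823551906	0.866751
PC	3.229057	0	4.229056657	2.080336
ACADVL	232.9049	129.287	1.795304533	0.844229
BCKDHA	19.85554	14.47789	1.347440581	0.430222
BCAT2	80.94945	0	81.9494509	6.356662
DLD	31.23854	8.77372	3.298492153	1.721807
GLDC	103.3204	5.884876	15.15210855	3.921447
SLC25A6	715.1606	479.5348	1.490340754	0.575642
SLC25A11	133.4975	0	134.4975213	7.071436
ALDH4A1	12.14576	1.389207	5.502143902	2.459994
HSPD1	183.9531	40.5506	4.451273652	2.154218
HSPA9	85.65878	13.06632	6.1607262	2.6231
TRAP1	157.0878	4.640674	28.02639676	4.808714
VDAC1	217.4922	69.43148	3.102195366	1.63329
VDAC2	111.4999	75.27239	1.474975787	0.560691
SOD2	57.46959	31.50043	1.799040268	0.847227
HSD17B4	23.51691	51.1044	0.470534	-1.08763
CHCHD3	38.77691	60.24344	0.649489	-0.62262
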