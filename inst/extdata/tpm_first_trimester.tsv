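gene	tpm_cyt	tpm_syn	ratio_printed	log2fc_printed
ATP5A1	10.85863	6.709574	1.618378086	0.69454869
SDHA	1.08374	0.887366	1.22129943	0.288416953
NDUFA12	3.312017	1.919608	1.725360662	0.786897968
PCK2	0.171777	0.036219	4.74273091	2.245718016
PDPR	0.043427	0.036219	1.199005005	0.261837681
LRPPRC	1.111726	0.597614	1.860274433	0.895515467
BCKDHA	0.36768	0.199205	1.845741039	0.884200154
BCAT2	0.658157	0.425574	1.54651804	0.629023662
DLD	1.248761	0.74249	1.681856344	0.750054482
GLDC	0.309778	0.126767	2.443686392	1.28905915
SLC25A11	1.438874	0.923585	1.557922844	0.639623785
ALDH4A1	0.673598	0.615723	1.093994109	0.12960497
HSPD1	16.14898	14.77736	1.092818614	0.128053963
HSPA9	4.72387	2.60777	1.811459723	0.857152728
TRAP1	1.365531	0.543285	2.513469752	1.329680327
VDAC1	5.048123	2.435729	2.07253042	1.051393277
VDAC2	2.148179	1.67513	1.282395263	0.358841002
HSPA5	20.69624	38.23823	0.541244746	-0.88564697
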