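R-HSA-449147	Signaling by Interleukins	IL1A	IL1B	IL2	IL4	IL4R	IL5	IL6	IL6R	IL10	IL12A	IL12B	IL13	IL17A	IL17F	IL18	IL19	IL20	IL21	IL22	IL23A	IL24	IL25	IL26	IL31	IL33	IL36A	IL36G	IL37	JAK1	JAK2	JAK3	TYK2	STAT1	STAT3	STAT6
R-HSA-6785807	Interleukin-4 and Interleukin-13 signaling	IL4	IL4R	IL13	STAT6	JAK1	JAK3	GATA3	CCL17	CCL22	FCER1A	TSLP	IL5	IL31
R-HSA-6783783	Interleukin-10 signaling	IL10	IL19	IL20	IL22	IL24	IL26	JAK1	TYK2	STAT3	TNF	IL1A	IL1B	CXCL8
R-HSA-877300	Interferon gamma signaling	IFNG	JAK1	JAK2	STAT1	CXCL9	CXCL10	CXCL11	ICAM1	MX1	OAS1	ISG15	HLA-B	HLA-C
R-HSA-447115	Interleukin-12 family signaling	IL12A	IL12B	IL23A	IL23R	JAK2	TYK2	STAT3	TBX21	RORC	IL17A
R-HSA-8854691	Interleukin-20 family signaling	IL19	IL20	IL22	IL24	IL26	STAT3	S100A7	S100A8	S100A9	DEFB4A
R-HSA-913531	Interferon Signaling	IFNG	IFNA1	IFNB1	JAK1	JAK2	TYK2	STAT1	ISG15	MX1	OAS1	IFI27	IFIH1	DDX58
R-HSA-380108	Chemokine receptors bind chemokines	CXCL1	CXCL8	CXCL9	CXCL10	CXCL11	CXCL12	CCL2	CCL5	CCL17	CCL20	CCL22	CCL27	CCR4	CCR6	CXCR3	CXCR4	CX3CL1	CX3CR1
R-HSA-451927	Interleukin-2 family signaling	IL2	IL2RA	IL2RG	IL4	IL7	IL9	IL15	IL21	IL21R	JAK1	JAK3	STAT3
R-HSA-1059683	Interleukin-6 signaling	IL6	IL6R	IL6ST	JAK1	JAK2	STAT3
R-HSA-157118	Signaling by NOTCH	NOTCH1	NOTCH2	NOTCH3	NOTCH4	JAG1	JAG2	DLL1	DLL4	RBPJ	HES1	HEY1	ADAM10	ADAM17	PSEN1	PSEN2	PSENEN	NCSTN	POFUT1	POGLUT1
R-HSA-6809371	Formation of the cornified envelope	KRT1	KRT5	KRT10	KRT14	FLG	FLG2	LOR	IVL	TGM1	TGM3	SPRR2A	LCE3B	LCE3D	CDSN	KLK5	KLK7	SPINK5
R-HSA-166658	Complement cascade	C3	C1QA	C5	C5AR1	CFB	CFH	MBL2
R-HSA-168898	Toll-like Receptor Cascades	TLR2	TLR4	TLR7	TLR9	MYD88	IRAK4	NFKB1	RELA	CXCL8	TNF
R-HSA-622312	Inflammasomes	NLRP1	NLRP3	AIM2	PYCARD	CASP1	IL1B	IL18
R-HSA-195721	Signaling by WNT	CTNNB1	WNT5A	LEF1	MYC	TP63
R-HSA-5632684	Hedgehog ligand biogenesis	SHH	PTCH1	SMO	GLI1
R-HSA-6805567	Keratinization	KRT1	KRT5	KRT6A	KRT10	KRT14	KRT16	KRT17	TGM1	TGM3	IVL	LOR	FLG
R-HSA-1280215	Cytokine Signaling in Immune system	IL1B	IL6	TNF	IFNG	IL17A	IL23A	IL12B	IL10	IL4	IL13	TSLP	IL33	IL25	TGFB1	JAK1	JAK2	STAT1	STAT3	STAT6	NFKB1
R-HSA-198933	Immunoregulatory interactions	CD200	CD200R1	CD274	PDCD1	CTLA4	TIGIT	LAG3	ICOS	CD80	CD86	CD28	CD40	CD40LG
GO:0034097	Response to cytokine	IL4R	IL6R	IL10	IL13	IL17A	IL22	IL23R	JAK1	JAK2	STAT1	STAT3	STAT6	TNF	IFNG	CXCL10	S100A8	S100A9	CCL2	CCL5	MX1
GO:0019221	Cytokine-mediated signaling pathway	IL1B	IL2	IL4	IL6	IL10	IL12B	IL13	IL17A	IL22	IL23A	TNF	IFNG	JAK1	JAK2	JAK3	TYK2	STAT1	STAT3	STAT6	NFKB1	RELA
GO:0071345	Cellular response to cytokine stimulus	IL4	IL6	IL13	IL17A	IL22	TNF	IFNG	STAT1	STAT3	STAT6	CCL2	CCL20	CXCL1	CXCL8	DEFB4A	S100A7
GO:0002376	Immune system process	CD2	CD4	CD8A	CD14	CD19	CD28	CD40	FOXP3	GATA3	TBX21	RORC	FCER1A	FCER1G	GZMB	PRF1	TLR2	TLR4	MYD88	C3	CFB	IL1B	IL6	TNF	IFNG
GO:0006952	Defense response	DEFB1	DEFB4A	CAMP	LCN2	LTF	PI3	S100A7	S100A8	S100A9	C3	C5	TLR2	TLR4	NOD2	NLRP3	CASP1	IL1B	TNF
GO:0009605	Response to external stimulus	TLR2	TLR4	TLR7	TLR9	NOD2	CAMP	DEFB4A	CXCL8	CCL20	VDR	AHR	MC1R	POMC
GO:0044419	Interspecies interaction between organisms	TLR2	TLR4	TLR9	NOD2	MYD88	CAMP	DEFB1	DEFB4A	LCN2	LTF	C3	MBL2	CLDN1	TJP1
GO:0070887	Cellular response to chemical stimulus	AHR	VDR	ESR1	MC1R	EGFR	FGFR2	MTOR	AKT1	PIK3CA	MAPK1	MAPK14	FOS	JUN	MYC
GO:0010033	Response to organic substance	VDR	ESR1	AHR	EGFR	AKT1	MTOR	FOS	JUN	TP53	BCL2	CASP8	FAS
GO:0051707	Response to other organisms	TLR2	TLR4	TLR7	TLR9	CAMP	DEFB1	DEFB4A	S100A7	S100A8	S100A9	LCN2	LTF	NOD2	C3
GO:0042060	Wound healing	EGFR	FGF7	FGFR2	VEGFA	TGFB1	MMP1	MMP9	TIMP1	CDH1	CTNNB1	ITGB2
GO:0008544	Epidermis development	KRT1	KRT5	KRT10	KRT14	FLG	LOR	IVL	TGM1	SPINK5	TP63	NOTCH1	JAG1	CDSN	DSG1	DSG3
GO:0045087	Innate immune response	TLR2	TLR4	TLR7	TLR9	MYD88	IRAK4	NOD2	NLRP3	AIM2	CASP1	C3	CFB	MBL2	DEFB4A	CAMP	ISG15	MX1	OAS1	DDX58	IFIH1
GO:0002250	Adaptive immune response	CD4	CD8A	CD19	CD28	CD40	CD40LG	CD80	CD86	CTLA4	PDCD1	ICOS	FOXP3	GATA3	TBX21	RORC	IL2	IL4	IL17A	IFNG
GO:0050728	Negative regulation of inflammatory response	IL10	IL37	TNFAIP3	TNIP1	NFKBIA	FOXP3	CD200	CD200R1
GO:0030216	Keratinocyte differentiation	KRT1	KRT10	FLG	LOR	IVL	TGM1	TGM3	SPRR2A	LCE3B	LCE3D	TP63	NOTCH1	HES1
GO:0019722	Calcium-mediated signaling	S100A7	S100A8	S100A9	CAMP	MALT1	CARD11
GO:0007219	Notch signaling pathway	NOTCH1	NOTCH2	NOTCH3	NOTCH4	JAG1	JAG2	DLL1	DLL4	RBPJ	HES1	HEY1	ADAM10	PSEN1	NCSTN
GO:0006955	Immune response	IL1A	IL1B	IL2	IL4	IL5	IL6	IL10	IL13	IL17A	IL22	TNF	IFNG	CXCL8	CXCL10	CCL2	CCL5	CCL17	CCL20	C3	TLR4
GO:0050900	Leukocyte migration	ICAM1	VCAM1	SELE	ITGB2	CXCL1	CXCL8	CXCL12	CCL2	CCL5	CCL20	CCR4	CCR6	CXCR3	CXCR4
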