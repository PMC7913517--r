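# canonical<TAB>aliases<TAB>flags (cs = force case-sensitive, block = never match)
# HGNC-style symbols for inflammatory skin disease; symbols <= 4 chars are
# case-sensitive automatically
IL1A	IL-1A	
IL1B	IL-1B	
IL1RN		
IL2	IL-2	
IL4	IL-4	
IL4R		
IL5	IL-5	
IL6	IL-6	
IL6R		
IL6ST		
IL7	IL-7	
IL9	IL-9	
IL10	IL-10	
IL12A		
IL12B		
IL13	IL-13	
IL15	IL-15	
IL17A	IL-17A	
IL17F	IL-17F	
IL18	IL-18	
IL18R1		
IL18RAP		
IL19	IL-19	
IL20	IL-20	
IL21	IL-21	
IL21R		
IL22	IL-22	
IL23A	IL-23A	
IL23R		
IL24	IL-24	
IL25	IL-25	
IL26	IL-26	
IL31	IL-31	
IL31RA		
IL33	IL-33	
IL36A		
IL36G		
IL36RN		
IL37	IL-37	
IL2RA		
IL2RG		
IL5RA		
TNF	TNF-alpha,TNFA	
LTA		
IFNG	IFN-gamma	
IFNA1		
IFNB1		
TGFB1	TGF-beta1	
TSLP		
CXCL1		
CXCL8	IL8,IL-8	
CXCL9		
CXCL10	IP-10	
CXCL11		
CXCL12		
CCL2	MCP-1	
CCL5	RANTES	
CCL17	TARC	
CCL20		
CCL22		
CCL27		
CCR4		
CCR6		
CXCR3		
CXCR4		
CX3CL1		
CX3CR1		
NOTCH1	TAN1	
NOTCH2		
NOTCH3		
NOTCH4		
JAG1		
JAG2		
DLL1		
DLL4		
RBPJ		
HES1		
HEY1		
ADAM10		
ADAM17	TACE	
PSEN1		
PSEN2		
PSENEN		
NCSTN	nicastrin	
POFUT1		
POGLUT1		
KRT1		
KRT5		
KRT6A		
KRT10		
KRT14		
KRT16		
KRT17		
FLG	filaggrin	
FLG2		
LOR	loricrin	
IVL	involucrin	
TGM1		
TGM3		
SPINK5		
LCE3B		
LCE3D		
SPRR2A		
S100A7	psoriasin	
S100A8		
S100A9		
DEFB1		
DEFB4A		
CAMP	LL-37,cathelicidin	
PI3	elafin	
SERPINB3		
SERPINB4		
LCN2		
LTF	lactoferrin	
CD2		
CD4		
CD8A		
CD14		
CD19		
CD28		
CD40		
CD40LG	CD154	
CD80		
CD86		
CD200	OX-2	
CD200R1		
CD207	langerin	
CD274	PD-L1	
DOK2		
FOXP3		
GATA3		
TBX21	T-bet	
RORC		
STAT1		
STAT3		
STAT6		
JAK1		
JAK2		
JAK3		
TYK2		
NFKB1		
RELA	p65	
NFKBIA		
TRAF3IP2	ACT1	cs
CARD11		
CARD14		
MALT1		
NLRP1		
NLRP3		
AIM2	AIM2	cs
PYCARD	ASC	cs
CASP1		
CASP8		
C3		
C1QA		
C5		
C5AR1		
CFB		
CFH		
MBL2		
TLR2		
TLR4		
TLR7		
TLR9		
MYD88		
IRAK4		
NOD2		
HLA-B		
HLA-C	HLA-Cw6	
ERAP1		
TNFAIP3	A20	
TNIP1		
IFIH1	MDA5	
DDX58	RIG-I	
RNF114		
OVOL1		
KIF3A		
TMEM232		
CLDN1		
TJP1	ZO-1	
GJB2	connexin 26	
ABCA12		
ALOX12B		
ALOXE3		
CERS3		
ELOVL4		
VDR		
CYP27B1		
FCER1A		
FCER1G		
MS4A2		
GZMB		
PRF1		
FASLG		
FAS	CD95	
BCL2		
MKI67	Ki-67	
EGFR		
FGF7	KGF	
FGFR2		
VEGFA		
HIF1A		
MTOR		
AKT1		
PIK3CA		
PTEN		
MAPK1	ERK2	
MAPK14	p38	
FOS	c-Fos	
JUN	c-Jun	
MYC	c-Myc	
TP53	p53	
TP63	p63	
CTNNB1	beta-catenin	
WNT5A		
LEF1	LEF1	cs
SHH		
PTCH1		
SMO	SMO	cs
GLI1		
KLK5		
KLK7		
CTSS		
MMP1		
MMP9		
TIMP1		
ICAM1		
VCAM1		
SELE	E-selectin	
ITGB2		
CDH1	E-cadherin	
DSG1		
DSG3		
DSC2		
PKP1		
CDSN	corneodesmosin	
CCHCR1		
CTLA4		
PDCD1	PD-1	
ICOS	ICOS	cs
TIGIT		
LAG3		
AHR	AHR	cs
POMC		
MC1R		
ESR1		
ISG15		
MX1		
OAS1		
IFI27		
IMPACT	IMPACT	cs
SET	SET	block
REST	REST	block
LARGE1	LARGE	block
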