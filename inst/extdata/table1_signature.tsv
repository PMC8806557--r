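gene1	gene2	coefficient
CD8A	CETP	-0.07
IDO1	TGFB3	-0.03
FCER1G	PTGDS	-0.01
IRF1	SEMA6A	-0.21
HLA-DQB1	S100A8	-0.16
IRF1	MET	-0.11
HLA-DQB1	CDH1	-0.02
JUN	SEMA6A	-0.06
HSPA2	CX3CL1	0.15
GNLY	SEMA4A	-0.03
HSPA2	FGFRL1	0.05
BPHL	CMTM8	0.01
CXCL14	RSAD2	0.02
MARCO	PLAUR	-0.02
CXCL1	ITK	0.02
CCL28	TRIM22	0.03
CCL8	APLNR	-0.17
IRF7	PIK3CD	-0.06
CCL8	TUBB3	-0.04
PDGFRB	TNFSF13B	0.02
S100A9	STAT1	0.04
GBP2	LTBR	-0.13
S100A9	RARRES3	0.01
CCR1	RAC3	-0.01
S100A8	IFIH1	0.10
CD79B	LTB	0.02
SLC22A17	CRABP2	-0.11
RAC3	SEMA3B	0.04
APOBEC3G	ANGPTL2	-0.01
RAC3	FGFRL1	0.04
PLAU	RARRES3	0.01
CD72	EDNRA	-0.06
NOX4	EDNRA	-0.12
IFITM1	GPI	-0.001
CRABP2	CYBB	0.09
SEMA3C	SEMA6A	-0.05
CYBB	CD79B	-0.01
TNC	CLEC11A	-0.07
IFIH1	BMPR2	-0.01
IL17D	SCG2	0.10
IDO1	EDNRA	-0.03
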