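TME_IE	synthetic stand-in for the published 134-gene TME subtype panel	COL1A1	COL1A2	COL3A1	COL5A1	COL5A2	COL6A3	COL8A1	COL10A1	COL11A1	FN1	FAP	ACTA2	TAGLN	PDGFRA	PDGFRB	THBS1	THBS2	SPARC	LUM	DCN	VCAN	POSTN	FBN1	MMP2	TIMP2	ZEB1	SNAI2	TWIST1	CDH11	PCOLCE	SFRP2	SFRP4	AEBP1	OLFML2B	CTHRC1	INHBA	BGN	MXRA8	PLOD2	LOXL2
TME_IS	synthetic stand-in for the published 134-gene TME subtype panel	IL1B	IL1A	IL1R1	CXCL8	CXCL1	CXCL2	CXCL5	CXCL6	CCL20	S100A8	S100A9	S100A12	FCGR3B	CSF3R	FPR1	TREM1	OSM	PTGS2	PLAUR
TME_IA	synthetic stand-in for the published 134-gene TME subtype panel	CD8A	CD8B	CD3D	CD3E	CD3G	CD2	CD27	CD28	GZMA	GZMB	GZMH	GZMK	GZMM	PRF1	GNLY	NKG7	KLRD1	KLRK1	KLRB1	IFNG	TBX21	EOMES	CXCL9	CXCL10	CXCL11	CXCL13	CCL5	CCR5	CXCR3	CXCR6	IL2RB	IL2RG	IL21R	LAG3	PDCD1	TIGIT	CTLA4	HAVCR2	BTLA	CD274	PDCD1LG2	IDO1	STAT1	IRF1	PSMB9	TAP1	TAP2	B2M	HLA-A	HLA-B	HLA-C	HLA-DRA	HLA-DRB1	HLA-DPA1	HLA-DPB1	HLA-DQA1	HLA-E	HLA-F	CIITA	UBD	GBP1	GBP4	GBP5	IL15	IL18R1	ICOS	TNFRSF9	TNFRSF18	CD40LG	SLAMF6	CST7	ZAP70	LCK	ITK	SH2D1A
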