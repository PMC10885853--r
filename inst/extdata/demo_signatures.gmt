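EMT_CORE	EMT	VIM	FN1	CDH2	SNAI1	SNAI2	TWIST1	ZEB1	ZEB2	MMP2	SPARC
MESENCHYMAL_MARKERS	mesenchymal	VIM	COL1A1	COL1A2	COL3A1	COL5A1	FBN1	LUM	DCN	THBS2	POSTN	FAP	PDGFRB
STEMNESS_CORE	stemness	PROM1	CD44	ALDH1A1	LGR5	SOX2	POU5F1	NANOG	KLF4
FIBROBLAST_MARKERS	cell_type	FAP	PDGFRA	PDGFRB	COL1A1	COL1A2	LUM	DCN	THY1	ACTA2
ENDOTHELIAL_MARKERS	cell_type	PECAM1	VWF	CDH5	KDR	CLDN5	ENG
TCELL_MARKERS	cell_type	CD3D	CD3E	CD2	CD8A	IL7R	TRAC
PROLIFERATION	process	MKI67	PCNA	TOP2A	BIRC5	CCNB1	AURKA	BUB1	TYMS
ECM	process	COL4A1	COL6A1	COL6A2	LAMA4	LAMB1	FBLN1	MMP14	TIMP1
EPITHELIAL_MARKERS	other	EPCAM	CDH1	KRT8	KRT18	KRT19	CLDN4
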