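gdT	gamma-delta T lineage programme	TRDC	TRGC1	TRGC2	KLRD1	B2M
MAIT	MAIT tissue programme	KLRB1	DPP4	CXCR6	IL7R
iNKT	invariant NKT programme	ZBTB16	CD1D	GZMK	IL2RB
pan_T	pan T-cell markers	CD3D	CD3E	CD2	CD7
fibroblast	fibroblast markers	COL1A1	COL1A2	PDGFRA	LUM	DCN
keratinocyte	keratinocyte markers	KRT14	KRT5	KRT10	KRT1	FLG
tissue_residency	tissue residency programme	CXCR6	IL7R	CD69	ITGAE	RGS1
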