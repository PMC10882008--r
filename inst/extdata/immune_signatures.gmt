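IFNG_SIGNALING	IFN-gamma signaling program (editable default; conventional literature members)	IFNG	STAT1	STAT2	IRF1	CXCL9	CXCL10	CXCL11	IDO1	GBP1	HLA-DRA
APM	Antigen-presentation machinery, HLA class I processing/presentation (editable default)	HLA-A	HLA-B	HLA-C	HLA-E	B2M	TAP1	TAP2	TAPBP	PSMB8	PSMB9	NLRC5
PROLIFERATION	Tumor proliferation program (editable default)	MKI67	CCNB1	BUB1	PLK1	TOP2A	AURKA	CDK1	CCNE1
CYTOLYTIC	Cytolytic effector genes	GZMA	PRF1
EXHAUSTION	T cell exhaustion checkpoint panel	PDCD1	LAG3	HAVCR2	KLRG1	TIGIT	CD244	CD160	BTLA	CTLA4	ENTPD1	ID2
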