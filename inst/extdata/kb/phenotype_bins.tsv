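# Activity-score -> metabolizer phenotype bins. Bounds are inclusive and
# partition the attainable 0.25-grid of diplotype scores for each gene.
# CYP2D6 follows the consensus convention: 0 PM; (0,1] IM; (1,2.25] NM; >2.25 UM.
gene_symbol	phenotype_label	lower_bound	upper_bound
CYP2D6	PM	0	0
CYP2D6	IM	0.25	1
CYP2D6	NM	1.25	2.25
CYP2D6	UM	2.5	9
CYP2C19	PM	0	0
CYP2C19	IM	0.25	1.5
CYP2C19	NM	1.75	2
CYP2C19	RM	2.25	2.5
CYP2C19	UM	2.75	9
CYP2C9	PM	0	0.5
CYP2C9	IM	0.75	1.5
CYP2C9	NM	1.75	9
TPMT	PM	0	0
TPMT	IM	0.25	1
TPMT	NM	1.25	9
NUDT15	PM	0	0
NUDT15	IM	0.25	1
NUDT15	NM	1.25	9
SLCO1B1	PM	0	0
SLCO1B1	IM	0.25	1
SLCO1B1	NM	1.25	9
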