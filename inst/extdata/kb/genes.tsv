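# Pharmacogene definitions: mechanistic category and phenotype system.
# metabolizer genes use additive star-allele activity scores; carrier genes
# use allele presence/absence.
gene_symbol	category	phenotype_system	uses_activity_score
CYP2D6	exposure	metabolizer	TRUE
CYP2C19	exposure	metabolizer	TRUE
CYP2C9	exposure	metabolizer	TRUE
TPMT	exposure	metabolizer	TRUE
NUDT15	exposure	metabolizer	TRUE
SLCO1B1	exposure	metabolizer	TRUE
HLA-B	safety	carrier	FALSE
IFNL3	response	carrier	FALSE
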