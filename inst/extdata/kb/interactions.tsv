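# Perpetrator co-medications causing CYP phenoconversion.
# strong_inhibitor x0, moderate_inhibitor x0.5, moderate_inducer x1.5,
# strong_inducer x2 on the activity score (multipliers live in code defaults).
perpetrator_drug	gene_symbol	strength
paroxetine	CYP2D6	strong_inhibitor
fluoxetine	CYP2D6	strong_inhibitor
bupropion	CYP2D6	strong_inhibitor
terbinafine	CYP2D6	strong_inhibitor
duloxetine	CYP2D6	moderate_inhibitor
cimetidine	CYP2D6	moderate_inhibitor
fluvoxamine	CYP2C19	strong_inhibitor
fluconazole	CYP2C19	moderate_inhibitor
rifampicin	CYP2C19	strong_inducer
rifampicin	CYP2C9	moderate_inducer
amiodarone	CYP2C9	moderate_inhibitor
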