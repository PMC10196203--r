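# Drug-gene pairs (curated CPIC-style snapshot). cpic_level A or A_B counts
# as "guideline available"; level B/other rows are carried for completeness
# but never qualify. gene_role encodes the mechanistic direction:
#   activating   = enzyme converts prodrug to active moiety
#   inactivating = enzyme/transporter clears the active drug
#   target       = response biomarker
#   immune_risk  = HLA-type severe-reaction risk
drug_name	gene_symbol	cpic_level	gene_role
codeine	CYP2D6	A	activating
tramadol	CYP2D6	A	activating
clomipramine	CYP2D6	A	inactivating
clomipramine	CYP2C19	A	inactivating
amitriptyline	CYP2D6	A	inactivating
amitriptyline	CYP2C19	A	inactivating
clopidogrel	CYP2C19	A	activating
warfarin	CYP2C9	A	inactivating
azathioprine	TPMT	A	inactivating
azathioprine	NUDT15	A	inactivating
allopurinol	HLA-B	A	immune_risk
abacavir	HLA-B	A	immune_risk
carbamazepine	HLA-B	A	immune_risk
simvastatin	SLCO1B1	A	inactivating
peginterferon	IFNL3	A_B	target
metoprolol	CYP2D6	B	activating
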