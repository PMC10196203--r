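# Star-allele / HLA-allele function assignments (curated snapshot).
# activity_value only for activity-score genes; copy-number suffixes (x2)
# carry the multiplied value. risk/non_risk only for carrier-system genes.
gene_symbol	allele	function_class	activity_value
CYP2D6	*1	normal	1
CYP2D6	*2	normal	1
CYP2D6	*9	decreased	0.5
CYP2D6	*10	decreased	0.25
CYP2D6	*17	decreased	0.5
CYP2D6	*41	decreased	0.5
CYP2D6	*3	no_function	0
CYP2D6	*4	no_function	0
CYP2D6	*5	no_function	0
CYP2D6	*6	no_function	0
CYP2D6	*1x2	increased	2
CYP2D6	*2x2	increased	2
CYP2D6	*4x2	no_function	0
CYP2C19	*1	normal	1
CYP2C19	*2	no_function	0
CYP2C19	*3	no_function	0
CYP2C19	*17	increased	1.5
CYP2C9	*1	normal	1
CYP2C9	*2	decreased	0.5
CYP2C9	*3	no_function	0
TPMT	*1	normal	1
TPMT	*2	no_function	0
TPMT	*3A	no_function	0
TPMT	*3B	no_function	0
TPMT	*3C	no_function	0
NUDT15	*1	normal	1
NUDT15	*2	no_function	0
NUDT15	*3	no_function	0
SLCO1B1	*1	normal	1
SLCO1B1	*1B	normal	1
SLCO1B1	*5	no_function	0
SLCO1B1	*15	no_function	0
HLA-B	B*58:01	risk
HLA-B	B*57:01	risk
HLA-B	B*15:02	risk
HLA-B	B*07:02	non_risk
HLA-B	B*08:01	non_risk
IFNL3	rs12979860T	risk
IFNL3	rs12979860C	non_risk
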