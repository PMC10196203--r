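drug,status,guideline,adequate_trial,problem,congruency,congruency_label,rationale
"codeine","current",1,1,1,-1,"incongruent","CYP2D6 *1/*1x2 UM (activating role) predicts adverse_effects; observed poor_efficacy => incongruent (-1)"
"clomipramine","current",1,1,1,1,"congruent","CYP2D6 *1/*1x2 UM (inactivating role) predicts poor_efficacy; CYP2C19 *1/*1 NM (inactivating role) predicts no problem; observed poor_efficacy => congruent (+1)"
PGxBS,0
interpretation,pgx_less_likely
testing_recommended,false
n_guideline_meds,2
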