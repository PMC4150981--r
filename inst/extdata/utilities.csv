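state,utility,se,distribution
at_risk,0.71,0.04,beta
diabetes,0.63,0.06,beta
chd_1,0.47,0.05,beta
chd_1plus,0.56,0.06,beta
stroke_1,0.50,0.05,beta
stroke_1plus,0.50,0.05,beta
colon_1,0.64,0.06,beta
colon_1plus,0.64,0.06,beta
dead,0.00,0.00,none
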