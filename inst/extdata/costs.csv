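item,annual_cost_eur,se_eur,distribution
diabetes,3312,331,gamma
chd_year1,4386,439,gamma
chd_followup,1183,118,gamma
stroke_year1,13319,1332,gamma
stroke_followup,4756,476,gamma
colon_year1,9575,958,gamma
colon_followup,9575,958,gamma
intervention_pedometer_year,35.00,3.50,gamma
intervention_other_year,21.30,2.13,gamma
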