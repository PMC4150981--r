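disease,sex,per_unit_reduction_pct,rr_reduction_pct,se_pct,distribution
diabetes,men,13.0,2.60,0.003,lognormal
diabetes,women,11.0,2.20,0.002,lognormal
chd,men,4.7,0.94,0.001,lognormal
chd,women,5.7,1.14,0.001,lognormal
stroke,men,6.0,1.20,0.001,lognormal
stroke,women,8.5,1.70,0.002,lognormal
colon,men,5.2,1.04,0.001,lognormal
colon,women,2.0,0.40,0.001,lognormal
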