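sex,age_lower,age_upper,diabetes_incidence,diabetes_fatality,chd_incidence,chd_fatality_year1,chd_fatality_followup,stroke_incidence,stroke_fatality_year1,stroke_fatality_followup,colon_incidence,colon_fatality,overall_mortality
men,20,24,0.06,0.12,0.01,5.50,4.87,0.02,13.00,0.16,0.01,6.62,0.08
men,25,29,0.10,0.13,0.02,5.50,4.87,0.03,13.00,0.18,0.01,6.62,0.09
men,30,34,0.17,0.13,0.05,5.50,4.87,0.05,13.00,0.18,0.01,6.62,0.09
men,35,39,0.28,0.19,0.10,5.50,4.87,0.07,13.00,0.26,0.03,6.62,0.12
men,40,44,0.48,0.26,0.19,5.50,4.87,0.11,13.00,0.36,0.04,6.62,0.15
men,45,49,0.78,0.44,0.35,5.50,4.87,0.16,13.00,0.61,0.09,6.62,0.24
men,50,55,1.18,0.74,0.41,5.50,4.87,0.25,36.00,1.03,0.16,7.70,0.39
men,56,59,1.65,1.19,0.63,15.30,13.56,0.37,36.00,1.65,0.26,7.70,0.61
men,60,64,2.08,1.82,0.89,15.30,13.56,0.55,24.00,2.53,0.37,7.70,0.90
men,65,69,2.46,2.58,1.17,15.30,13.56,0.83,24.00,3.59,0.60,9.77,1.28
women,20,24,0.05,0.04,0.01,7.30,7.74,0.02,25.00,0.06,0.01,5.67,0.03
women,25,29,0.08,0.06,0.02,7.30,7.74,0.03,25.00,0.08,0.01,5.67,0.04
women,30,34,0.14,0.06,0.03,7.30,7.74,0.04,25.00,0.09,0.01,5.67,0.04
women,35,39,0.23,0.11,0.05,7.30,7.74,0.06,25.00,0.15,0.03,5.67,0.07
women,40,44,0.39,0.16,0.08,7.30,7.74,0.09,25.00,0.23,0.04,5.67,0.10
women,45,49,0.63,0.27,0.13,7.30,7.74,0.13,25.00,0.38,0.09,5.67,0.16
women,50,55,0.96,0.44,0.16,7.30,7.74,0.20,18.00,0.63,0.16,6.89,0.27
women,56,59,1.34,0.64,0.27,17.90,18.97,0.30,18.00,0.90,0.26,6.89,0.37
women,60,64,1.69,0.98,0.41,17.90,18.97,0.44,23.00,1.39,0.38,6.89,0.54
women,65,69,2.00,1.36,0.62,17.90,18.97,0.67,23.00,1.93,0.60,8.91,0.74
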