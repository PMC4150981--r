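# lifestyleCEA

Markov cohort cost-effectiveness model of a physical-activity and
healthy-eating promotion programme for individuals with mental disorders.

People with severe mental disorders carry a substantially higher burden of
overweight and obesity than the general population, with the downstream
risks of type 2 diabetes, coronary heart disease (CHD), stroke and colon
cancer. Lifestyle promotion programmes in this population produce small
but real reductions in body mass index (BMI); whether those reductions
are worth paying for is a question for decision-analytic modelling. This
package implements such a model for health economists and HTA analysts:
a nine-state Markov cohort engine, an economic layer, the published
scenario analyses, and one-way plus probabilistic sensitivity analysis.

## The model in brief

A cohort starts disease-free ("at risk") and moves each year over the
states

```
at_risk, diabetes, chd_1, chd_1plus, stroke_1, stroke_1plus,
colon_1, colon_1plus, dead
```

driven by age- and sex-specific annual incidence and case-fatality
probabilities (5-year bands, ages 20–69, clamped above). First-year
disease states are one-cycle tunnels; death is absorbing. The
intervention arm scales the at-risk → disease transitions by
1 − (per-BMI-unit risk reduction × BMI change): a BMI change of
0.20 kg/m² gives, e.g., a 2.60% relative reduction of diabetes risk in
men. Each arm is summarised over 20 annual cycles as discounted QALYs
(utilities weighted, 1.5%/year) and discounted payer costs (disease state
costs plus the yearly programme cost of 35.00€ in pedometer years and
21.30€ otherwise, 3%/year), and the arms are compared by the incremental
cost-effectiveness ratio

ICER = (cost_I − cost_C) / (QALY_I − QALY_C)  [€/QALY],

against a willingness-to-pay threshold of 30,000€/QALY. The cohort start
age — the model's only free parameter — is calibrated once per sex by a
documented grid search (men 47, women 48). The methods vignette
(`vignettes/cohort-model-methods.Rmd`) derives every convention and
interpretation choice.

## Worked example

```r
library(lifestyleCEA)
params <- default_parameters()      # bundled published parameterisation

cmp <- run_comparison(params, "men")
print(cmp$control)
#> <economic_outcome> men / control (start age 47, 20 years)
#>   discounted: 11.7206 QALYs, 8188.52 EUR, 16.8958 life-years
print(cmp$icer)
#> <icer_result> men, scenario base
#>   delta cost 213.21 EUR, delta QALY 0.00781 -> 27299 EUR/QALY
```

Treatment as usual accrues 11.72 discounted QALYs and 8,189€ of
discounted disease cost per man; the programme buys 0.0078 extra QALYs
for 213€ extra cost, i.e. about 27,300€ per QALY — borderline
cost-effective at the 30,000€/QALY threshold (women land near
39,900€/QALY, above it).

```r
run_scenario_suite(params)[, c("scenario", "sex", "delta_qaly",
                               "delta_cost", "icer")]
#>              scenario   sex delta_qaly delta_cost   icer
#> 1                base   men   0.007810        213  27299
#> 3  s1_full_compliance   men   0.012910        124   9609
#> 5     s2_twice_yearly   men   0.007810        520  66627
#> 7     s3_utility_gain   men   0.068215        213   3126
#> 9        s4_five_year   men   0.000442        100 226067
```

Full compliance (BMI change 0.33) or crediting a small direct utility
gain per BMI unit makes the programme clearly cost-effective; truncating
the horizon to five years makes it clearly not — the costs are yearly but
the health benefits compound.

```r
psa <- run_psa(params, sex = "men", n = 10000, seed = 1)
print(psa)
#> <psa_result> men, scenario base, 10000 draws (seed 1)
#>   mean dQALY 0.0078 (95% CI 0.0017-0.0138)
#>   mean dCost 214 EUR (95% CI 159-271)
#>   mean ICER 27238 EUR/QALY (per-draw 95% CI 13728-105014, median 26981)
#>   cost-effective at 30000 EUR/QALY: 59.5% of draws

tornado(params, sex = "men")[1:2, c("parameter", "icer_low", "icer_high")]
#>             parameter icer_low icer_high
#> 1 intervention_effect    46543     16936
#> 2   intervention_cost    13863     40735
```

The probabilistic analysis samples every published mean/SE pair (costs
gamma, utilities beta, risk reductions lognormal) and summarises the
10,000 incremental outcomes; `ce_plane(psa)` returns the
cost-effectiveness-plane points. The tornado confirms that the
intervention effect and the programme cost dominate the parameter
uncertainty.

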