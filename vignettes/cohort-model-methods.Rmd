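---
title: "Methods: a Markov cohort model for lifestyle promotion in mental health care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model for lifestyle promotion in mental health care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifestyleCEA)
```

## The decision problem

Individuals with severe mental disorders carry a markedly higher burden of
overweight and obesity than the general population, and with it excess
risks of type 2 diabetes, coronary heart disease (CHD), stroke and colon
cancer. `lifestyleCEA` models the long-term cost-effectiveness, from a
public-payer perspective, of a yearly repeated 10-week physical-activity
and healthy-eating programme for this population. The programme's measured
effect is a small mean reduction in body mass index (BMI); the model
translates that reduction into disease risk reductions, propagates a
cohort through disease and death over 20 annual cycles, and compares the
intervention arm against treatment as usual by the incremental
cost-effectiveness ratio

ICER = (cost_I − cost_C) / (QALY_I − QALY_C),

in euro per quality-adjusted life year (QALY).

## Model structure

The cohort moves over a nine-state space: `at_risk`, `diabetes`, `chd_1`,
`chd_1plus`, `stroke_1`, `stroke_1plus`, `colon_1`, `colon_1plus`, `dead`.
The first-year disease states are strict one-cycle tunnels: a newly
diagnosed individual spends exactly one cycle there and then either dies
(first-year case fatality) or moves to the corresponding follow-up state.
Death is absorbing. Diabetic individuals face an additional colon-cancer
transition; no other transitions between disease branches are permitted,
and comorbidity combinations are not modelled (the diabetes state cost
already averages over macrovascular complications).

Transition probabilities are age- and sex-specific annual probabilities
over 5-year age bands (20–24 … 65–69), read as step functions of attained
age. The matrix for cycle *t* uses age `start_age + t − 1`; ages beyond
the top band clamp to it, which is the least-assumption extrapolation
available when a 20-year horizon outruns the table. Case-fatality
probabilities of disease states are used as the *total* per-cycle death
probability of that state — they already embed the elevated background
mortality of the diseased (1.4× for diabetes, 2× for stroke) — so
background mortality is not added on top, avoiding double counting.
Competing risks within a row are combined additively with the residual
mass as self-transition; a row exceeding probability mass 1 aborts the run
rather than being renormalised silently.

### Reading of the incidence table

The bundled incidence/fatality table lists *the transition probabilities
used by the model*, i.e. with the mental-disorder relative risks (diabetes
1.77, stroke 1.77, CHD 1.42 under age 50 and 1.01 from 50, colon cancer
2.90) already embedded. This reading was selected because applying those
relative risks a second time at run time produces control-arm costs
incompatible with the published totals at every candidate start age,
whereas the embedded reading reproduces the published women's base case to
within 0.01% (costs) and 0.6% (ICER). For users who supply a table of raw
general-population risks, the configuration switch
`options$apply_incidence_rr: yes` restores the run-time multiplication,
and the `relative_risks` block documents the factors either way.

### The diabetes-to-colon-cancer transition

Diabetic individuals have 1.33 times the colon-cancer risk of the
non-diabetic. The bundled default applies this factor to the at-risk →
colon-cancer probability (`diabetes_colon_basis: colon`). The alternative
literal composition — 1.33 times the at-risk → *diabetes* probability —
is available behind the same switch, but it implies a 1–3% annual
colon-cancer risk for diabetics, one to two orders of magnitude above the
tabulated colon-cancer incidence, and it fits the published results worse
in every scenario.

## Intervention effect

The trial measured a mean between-group BMI change of 0.20 kg/m² (0.33
kg/m² among completers). Published per-BMI-unit risk reductions (diabetes
13.0%/11.0% for men/women, CHD 4.7%/5.7%, stroke 6.0%/8.5%, colon cancer
5.2%/2.0%) are multiplied by the BMI change to give total relative risk
reductions (e.g. diabetes, men: 13.0% × 0.20 = 2.60%), which scale the
at-risk → disease transitions of the intervention arm from cycle 1 onward
for the whole horizon — the programme is assumed to be repeated every year
with undiminished effect. Whether a 10-week programme can hold its effect
for 20 years is the model's single strongest assumption; the 5-year
horizon scenario exists precisely as the conservative counterpart.

## Economic accumulation

* **Utilities** (QALY weights): at risk 0.71; diabetes 0.63; CHD 0.47
  first year, 0.56 after; stroke 0.50; colon cancer 0.64; dead 0.
  Discounted at 1.5% per year. Utilities are flat in age.
* **State costs** (year-2011 euro, per year): diabetes 3,312; CHD 4,386
  then 1,183; stroke 13,319 then 4,756; colon cancer 9,575 (both states);
  at risk and dead carry none. Discounted at 3% per year.
* **Programme cost**: pedometer 13.70€ (durable, five-year life), staff
  20.57€, administration 0.48€, manual 0.25€ — 35.00€ in years 1, 6, 11,
  16 and 21.30€ otherwise, charged to the surviving fraction of the
  intervention cohort each year (everyone is re-offered the programme; an
  `at_risk`-only charging switch exists).

The accumulation convention values **both endpoints** of the trace: the
state vector at cycle *t* (t = 0 … horizon) contributes with discount
factor (1+r)^−t, and the year-*y* programme cost is charged against the
year-start vector with factor (1+r)^−(y−1). This convention was selected
by calibration: under a 5-year horizon the published control arm accrues
4.05 QALYs, which exceeds the ceiling of any 5-term accumulation
(0.71 × 4.853 = 3.45) and is matched almost exactly by the 6-term
both-endpoints sum. The spec-style alternative (cycles 1..H at
(1+r)^−(t−1)) remains available as `options$accumulation:
transitions_only`. Life-years are discounted at the QALY rate by default;
this reproduces the published life-year totals (16.6/17.2 discounted
years) where undiscounted life-years do not. No half-cycle correction is
applied anywhere — the published totals are only consistent with whole-
cycle valuation.

## Calibration of the start age

The source material never states the cohort's starting age, which is
therefore the model's one free parameter. `calibrate_start_age()` runs
the control arm at every integer age 20–65 and scores each candidate by
the summed squared relative error of control-arm discounted QALYs and
costs against the published base-case totals (men 11.59 QALYs / 8,352€;
women 12.04 / 7,688€). The search selects **47 for men and 48 for
women**; the objective was fixed before any scenario or sensitivity
output was inspected, and the scenario suite is run under the same
calibration without re-tuning. A single-age cohort is used throughout; a
mixed-age cohort option is deliberately not implemented, since no age
distribution is available to parameterise it.

```{r calibration, eval = FALSE}
params <- default_parameters()
calibrate_start_age(params, "men")$start_age    # 47
calibrate_start_age(params, "women")$start_age  # 48
```

## Scenarios

| id | change relative to base case |
|----|------------------------------|
| `s1_full_compliance` | BMI change 0.33 kg/m² |
| `s2_twice_yearly` | programme twice a year: staff/administration/manual doubled (42.60€; 56.30€ in pedometer years), pedometer durable, effect unchanged |
| `s3_utility_gain` | +0.021 utility per BMI unit lost, intervention arm, at-risk state only (never in disease states, to limit double counting of the health gain) |
| `s4_five_year` | horizon 5 years |

The twice-yearly costing treats the pedometer as durable equipment rather
than doubling it; doubling everything is available via `options$s2_rule:
double_all`. Under the bundled calibration the model reproduces the
published base case and scenarios 1–3 within ±10%; the published 5-year
scenario row is not reproducible within that band by any configuration
that also reproduces the base case (its control cost exceeds the model's
5-year accrual by over 20% even though the 20-year totals agree within
2%, and its incremental cost equals the maximum possible programme charge
with zero disease savings), so the 5-year comparison is reported as
computed, about 19% above the published ratio.

## Sensitivity analysis

**One-way (tornado).** Each key parameter — intervention effect,
intervention cost, each disease cost, each risk reduction — is scaled to
70% and 130% of its base value with everything else fixed, the full
deterministic pipeline is re-run at both ends, and parameters are ranked
by the width of the resulting ICER range. The range is a screening
device, not an uncertainty statement.

**Probabilistic (PSA).** Every published mean/SE pair is sampled by
method-of-moments fits: costs and programme costs from gamma
(shape = (m/s)², scale = s²/m), utilities from beta
(α+β = m(1−m)/s² − 1), total risk reductions from lognormal
(σ² = ln(1+s²/m²), μ = ln m − σ²/2); an SE of zero gives a point mass.
Parameters are drawn independently (no correlation structure is
published) in a fixed documented order from one seeded generator, so runs
are bit-reproducible. The control trace does not depend on sampled
quantities and is computed once; each draw re-propagates the intervention
arm and re-prices both arms. Draws whose at-risk row would exceed
probability mass 1 are rejected and redrawn, with the count reported.

The published risk-reduction SEs (e.g. 0.003 against a mean of 2.60) are
read on the same percent scale as their means; the alternative
fraction-of-unity reading (100× larger) is available via
`options$rr_reduction_se_scale`, but it implies an incremental-QALY
spread far narrower than the published credible interval, so the
as-printed reading is the default.

The headline PSA ICER is the ratio of mean incremental cost to mean
incremental QALYs. The mean of per-draw ratios is reported only as a
diagnostic: a ratio whose denominator can approach zero has no finite
expectation, and its sample mean does not stabilise even at 10,000 draws
(it can change sign from one seed to the next), whereas the ratio of
means and the per-draw median agree with each other and with the
published summary. Per-draw 2.5/97.5 percentiles provide the credible
intervals, and the cost-effectiveness plane reports each draw's
(ΔQALY, ΔCost) against the willingness-to-pay line
ΔCost = 30,000 × ΔQALY.

## Validation machinery

* `microsim_oracle()` re-simulates the cohort as exchangeable individuals
  by multinomial state-jump sampling through the same cycle matrices and
  must agree with `run_cohort()` to binomial Monte-Carlo error; the test
  suite checks per-cell agreement at n = 50,000 on the 3-standard-error
  scale (with ~190 live cells, roughly half a cell is expected beyond
  3 SE by chance, so the assertion allows 1% of cells between 3 and
  4.5 SE).
* `perturbed_parameters()` generates random valid parameter sets by
  multiplying every input by independent uniform factors and repairing
  the result to the declared invariants; property tests run these
  end-to-end. The generator varies magnitudes, not structure: it does not
  emulate correlated epidemiological errors, secular trends, or
  non-constant effects, so passing property tests demonstrate numerical
  robustness, not real-world validity.
* The written fixture bundle round-trips value-identically, and every
  bundled cell is kept at its printed precision (percent scale, two
  decimals) so provenance stays auditable.

## Numerical choices and degenerate inputs

Occupancy row sums are enforced to 1 within 1e-12 at matrix construction
and 1e-10 along traces. A horizon of 0 returns the initial state only. A
BMI change of 0 makes the arms bit-identical; with programme components
also zeroed the incremental outcomes are exactly 0 and the ICER is
reported as `indeterminate` rather than divided. Dominance is classified
before any division. Ages below the lowest tabulated band raise an error
rather than clamp, because extrapolating incidence downward would be
invisible in the outputs. Beta fits with SE² ≥ m(1−m) are rejected as
infeasible rather than truncated.

## Problem sizes

The deterministic pipeline (one comparison: two arms × 20 cycles) runs in
milliseconds; the bundled analyses use the full published sizes — 10,000
PSA draws, 50,000 microsimulated individuals — and the whole test suite
completes in well under a minute on a single CPU.

## Known limitations

* Single start age per sex, calibrated, not published.
* Flat utilities by age; payer-perspective costs only; year-2011 euros
  with no inflation or currency adjustment.
* Effect persistence under yearly repetition is assumed, not evidenced;
  effect decay is deliberately not modelled (no published decay rate).
* Independence of sampled parameters in the PSA.
* No cost-effectiveness acceptability curve (single 30,000€/QALY
  threshold line only).
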