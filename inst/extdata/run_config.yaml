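# Run configuration for the lifestyle health-promotion cohort model.
# Probabilities in the CSV tables are stored as percentages exactly as
# published; they are converted to fractions when loaded.
horizon: 20
bmi_change: 0.20
threshold_eur_per_qaly: 30000
# Start ages selected by grid search over 20..65 against the published
# control-arm QALY and cost totals (see calibrate_start_age()).
start_age:
  men: 47
  women: 48
discount:
  cost: 0.03
  qaly: 0.015
relative_risks:
  diabetes: 1.77
  stroke: 1.77
  chd_young: 1.42
  chd_old: 1.01
  chd_age_cutoff: 50
  colon: 2.90
  diabetes_to_colon: 1.33
intervention_components_eur:
  pedometer: 13.70
  staff: 20.57
  admin: 0.48
  manual: 0.25
pedometer_life_years: 5
utility_gain_per_bmi_unit: 0.021
calibration_targets:
  men:
    control_qalys: 11.59
    control_cost: 8352
  women:
    control_qalys: 12.04
    control_cost: 7688
options:
  # both_endpoints: value both the cycle-0 and the cycle-H state vectors,
  # discounting cycle t at (1+r)^-t; transitions_only: cycles 1..H at
  # (1+r)^-(t-1).
  accumulation: both_endpoints
  # The incidence table above lists the transition probabilities used by
  # the model, i.e. with the mental-disorder relative risks already
  # embedded; set TRUE for tables of raw general-population risks, to
  # which the relative_risks block is then applied at run time.
  apply_incidence_rr: no
  # Basis for the diabetes -> colon-cancer transition: "colon" multiplies
  # the at-risk -> colon-cancer probability by 1.33; "diabetes" multiplies
  # the at-risk -> diabetes probability instead.
  diabetes_colon_basis: colon
  # Scale of the published SEs of the relative-risk reductions: "percent"
  # reads them on the same percent scale as the means; "fraction" reads them
  # as fractions of unity (i.e. 100x larger on the percent scale).
  rr_reduction_se_scale: percent
  # Charge the yearly programme cost to the whole surviving cohort ("alive")
  # or only to the disease-free cohort ("at_risk").
  charge_intervention_to: alive
  # Twice-yearly programme costing: "durable_pedometer" doubles staff,
  # admin and manual costs only; "double_all" doubles the pedometer too.
  s2_rule: durable_pedometer
  # Discount life-years at the QALY rate ("qaly_rate") or not at all ("none").
  life_year_discounting: qaly_rate
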