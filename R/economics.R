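#' Discount factor for a 1-based model year
#'
#' Under the default convention the first year is undiscounted:
#' factor = (1 + rate)^-(cycle - 1). The alternative `"end_year"`
#' convention discounts every year once more: (1 + rate)^-cycle.
#'
#' @param rate Annual discount rate (fraction, >= 0).
#' @param cycle 1-based year.
#' @param convention `"first_year_undiscounted"` (default) or `"end_year"`.
#' @return The discount factor.
#' @export
discount_factor <- function(rate, cycle,
                            convention = c("first_year_undiscounted",
                                           "end_year")) {
  convention <- match.arg(convention)
  stopifnot(rate >= 0, all(cycle >= 1))
  k <- if (convention == "first_year_undiscounted") cycle - 1 else cycle
  (1 + rate)^(-k)
}

#' Per-year programme cost schedule
#'
#' The programme costs 35.00 euro per participant in pedometer years
#' (a pedometer lasts five years, so years 1, 6, 11, 16 under the default
#' life) and 21.30 euro in all other years (staff, administration and
#' manual only). The twice-yearly scenario doubles the staff,
#' administration and manual components while keeping one durable
#' pedometer per five years (56.30 / 42.60 euro); the `"double_all"`
#' option doubles the pedometer too.
#'
#' @param params A `parameter_set`.
#' @param horizon Number of model years.
#' @param scenario A scenario from [make_scenario()].
#' @return Numeric vector of length `horizon`: cost charged in year y.
#' @export
intervention_cost_schedule <- function(params, horizon,
                                       scenario = make_scenario("base")) {
  comp <- params$config$intervention_components_eur
  life <- params$config$pedometer_life_years
  other <- comp$staff + comp$admin + comp$manual
  pedometer <- comp$pedometer
  if (identical(scenario$cost_rule, "twice_yearly")) {
    if (identical(params$config$options$s2_rule, "double_all")) {
      pedometer <- 2 * pedometer
    }
    other <- 2 * other
  }
  y <- seq_len(horizon)
  ifelse((y - 1) %% life == 0, pedometer + other, other)
}

#' Accumulate discounted QALYs, costs and life-years over a cohort trace
#'
#' Values both endpoints of every cycle by default: the state vector at
#' cycle t (t = 0..horizon) contributes its utilities discounted at the
#' QALY rate by (1+r)^-t and its disease costs discounted at the cost rate
#' likewise; the programme cost for year y (intervention arm only) is
#' charged at the start of the year, i.e. against the cycle y-1 state
#' vector with factor (1+r)^-(y-1), weighted by the surviving fraction.
#' The `"transitions_only"` accumulation option instead values cycles
#' 1..horizon with factor (1+r)^-(t-1). The utility-gain scenario adds
#' `utility_gain_per_bmi_unit * bmi_change` to the at-risk utility in the
#' intervention arm only.
#'
#' @param trace A `cohort_trace`.
#' @param params A `parameter_set`.
#' @param scenario A scenario from [make_scenario()].
#' @param cost_draw,utility_draw Optional named vectors overriding the
#'   deterministic state costs (canonical state order) and utilities; used
#'   by the probabilistic sensitivity analysis.
#' @param schedule_draw Optional length-2 vector `c(pedometer, other)`
#'   overriding the two programme year-costs.
#' @return An `economic_outcome`: list with discounted and undiscounted
#'   QALYs, costs and life-years and a per-cycle breakdown.
#' @export
accumulate_outcomes <- function(trace, params,
                                scenario = make_scenario("base"),
                                cost_draw = NULL, utility_draw = NULL,
                                schedule_draw = NULL) {
  arm <- attr(trace, "arm")
  horizon <- nrow(trace) - 1
  cfg <- params$config

  u <- if (is.null(utility_draw)) state_utility_vector(params) else utility_draw
  cst <- if (is.null(cost_draw)) state_cost_vector(params) else cost_draw
  if (isTRUE(scenario$utility_gain) && arm == "intervention")
    u[["at_risk"]] <- min(1, u[["at_risk"]] +
                            cfg$utility_gain_per_bmi_unit * scenario$bmi_change)

  occ <- unclass(trace)[, state_names(), drop = FALSE]
  alive <- 1 - occ[, "dead"]

  both_ends <- !identical(cfg$options$accumulation, "transitions_only")
  if (both_ends) {
    idx <- seq_len(horizon + 1)          # cycles 0..H
    expo <- 0:horizon
  } else {
    idx <- seq_len(horizon) + 1          # cycles 1..H
    expo <- 0:(horizon - 1)
  }
  dq <- (1 + cfg$discount$qaly)^(-expo)
  dc <- (1 + cfg$discount$cost)^(-expo)
  dl <- if (identical(cfg$options$life_year_discounting, "none")) {
    rep(1, length(expo))
  } else dq

  qaly_cycle <- as.vector(occ[idx, , drop = FALSE] %*% u)
  dcost_cycle <- as.vector(occ[idx, , drop = FALSE] %*% cst)

  # programme cost: years 1..horizon charged against the year-start state
  prog_cycle <- numeric(length(idx))
  if (arm == "intervention" && horizon >= 1) {
    sched <- intervention_cost_schedule(params, horizon, scenario)
    if (!is.null(schedule_draw)) {
      comp <- cfg$intervention_components_eur
      base_ped <- comp$pedometer + comp$staff + comp$admin + comp$manual
      base_oth <- comp$staff + comp$admin + comp$manual
      base_sched <- intervention_cost_schedule(params, horizon,
                                               make_scenario("base"))
      # map each year to its drawn value, preserving any scenario scaling
      sched <- ifelse(base_sched == base_ped,
                      sched / base_ped * schedule_draw[1],
                      sched / base_oth * schedule_draw[2])
    }
    weight <- if (identical(cfg$options$charge_intervention_to, "at_risk")) {
      occ[seq_len(horizon), "at_risk"]
    } else {
      alive[seq_len(horizon)]
    }
    charged <- sched * weight                       # year y at cycle y-1
    if (both_ends) prog_cycle[seq_len(horizon)] <- charged
    else {
      # transitions_only: year y valued with cycle-y state, factor (1+r)^-(y-1)
      prog_cycle <- charged
    }
  }

  per_cycle <- data.frame(
    cycle = if (both_ends) 0:horizon else 1:horizon,
    qalys = qaly_cycle * dq,
    disease_cost = dcost_cycle * dc,
    programme_cost = prog_cycle * dc,
    life_years = alive[idx] * dl)

  structure(list(
    qalys = sum(per_cycle$qalys),
    costs = sum(per_cycle$disease_cost + per_cycle$programme_cost),
    life_years = sum(per_cycle$life_years),
    qalys_undiscounted = sum(qaly_cycle),
    costs_undiscounted = sum(dcost_cycle + prog_cycle),
    life_years_undiscounted = sum(alive[idx]),
    per_cycle = per_cycle,
    arm = arm, sex = attr(trace, "sex"),
    start_age = attr(trace, "start_age"),
    horizon = horizon, scenario_id = scenario$id),
    class = "economic_outcome")
}

#' @export
print.economic_outcome <- function(x, ...) {
  cat(sprintf("<economic_outcome> %s / %s (start age %d, %d years)\n",
              x$sex, x$arm, x$start_age, x$horizon))
  cat(sprintf("  discounted: %.4f QALYs, %.2f EUR, %.4f life-years\n",
              x$qalys, x$costs, x$life_years))
  invisible(x)
}

#' Incremental cost-effectiveness ratio of intervention versus control
#'
#' ICER = (cost_I - cost_C) / (QALY_I - QALY_C). A zero QALY difference is
#' reported as `indeterminate` (no division); a cheaper and more effective
#' intervention as `dominant`; a costlier and less effective one as
#' `dominated`.
#'
#' @param intervention,control `economic_outcome` objects from the same
#'   sex, start age and horizon (mismatches are an error).
#' @return An `icer_result` with `delta_cost`, `delta_qaly`, `icer` and
#'   `classification`.
#' @export
compute_icer <- function(intervention, control) {
  stopifnot(inherits(intervention, "economic_outcome"),
            inherits(control, "economic_outcome"))
  for (f in c("sex", "start_age", "horizon"))
    if (!identical(intervention[[f]], control[[f]]))
      stop("mismatched run configurations: ", f, " differs between arms")
  dc <- intervention$costs - control$costs
  dq <- intervention$qalys - control$qalys
  cls <- if (dq == 0) "indeterminate"
  else if (dc < 0 && dq > 0) "dominant"
  else if (dc > 0 && dq < 0) "dominated"
  else "ratio"
  structure(list(
    delta_cost = dc, delta_qaly = dq,
    icer = if (dq != 0) dc / dq else NA_real_,
    classification = cls,
    sex = intervention$sex, scenario_id = intervention$scenario_id),
    class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("<icer_result> %s, scenario %s\n", x$sex, x$scenario_id))
  cat(sprintf("  delta cost %.2f EUR, delta QALY %.5f -> %s\n",
              x$delta_cost, x$delta_qaly,
              if (x$classification == "ratio")
                sprintf("%.0f EUR/QALY", x$icer) else x$classification))
  invisible(x)
}
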