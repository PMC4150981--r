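#' Construct a scenario configuration
#'
#' Five published configurations are available by id:
#' \describe{
#'   \item{base}{BMI change 0.20 kg/m2, 20-year horizon.}
#'   \item{s1_full_compliance}{BMI change 0.33 kg/m2 (programme
#'     completers), otherwise as base.}
#'   \item{s2_twice_yearly}{programme offered twice a year: staff,
#'     administration and manual costs doubled, BMI change kept at 0.20.}
#'   \item{s3_utility_gain}{adds 0.021 QALY-weight per BMI unit lost to
#'     the at-risk utility of the intervention arm.}
#'   \item{s4_five_year}{5-year horizon, otherwise as base.}
#' }
#' Short aliases `"s1"` .. `"s4"` are accepted. A `"custom"` scenario takes
#' its settings from the arguments.
#'
#' @param id Scenario id or alias.
#' @param bmi_change,horizon,utility_gain,cost_rule Overrides for a custom
#'   scenario (`cost_rule` is `"standard"` or `"twice_yearly"`).
#' @param params Optional `parameter_set` supplying the configured defaults
#'   for BMI change and horizon.
#' @return A `scenario` object.
#' @export
make_scenario <- function(id = "base", bmi_change = NULL, horizon = NULL,
                          utility_gain = NULL, cost_rule = NULL,
                          params = NULL) {
  alias <- c(s1 = "s1_full_compliance", s2 = "s2_twice_yearly",
             s3 = "s3_utility_gain", s4 = "s4_five_year")
  if (id %in% names(alias)) id <- alias[[id]]
  known <- c("base", unname(alias), "custom")
  if (!id %in% known)
    stop("unknown scenario id: ", id, " (known: ",
         paste(known, collapse = ", "), ")")

  base_bmi <- if (!is.null(params)) params$config$bmi_change else 0.20
  base_h <- if (!is.null(params)) params$config$horizon else 20L

  sc <- list(id = id, bmi_change = base_bmi, horizon = base_h,
             utility_gain = FALSE, cost_rule = "standard")
  if (id == "s1_full_compliance") sc$bmi_change <- 0.33
  if (id == "s2_twice_yearly") sc$cost_rule <- "twice_yearly"
  if (id == "s3_utility_gain") sc$utility_gain <- TRUE
  if (id == "s4_five_year") sc$horizon <- 5L
  if (id == "custom") {
    if (!is.null(bmi_change)) sc$bmi_change <- bmi_change
    if (!is.null(horizon)) sc$horizon <- horizon
    if (!is.null(utility_gain)) sc$utility_gain <- utility_gain
    if (!is.null(cost_rule)) sc$cost_rule <- match.arg(cost_rule,
                                                      c("standard", "twice_yearly"))
  } else if (!is.null(bmi_change) || !is.null(horizon) ||
             !is.null(utility_gain) || !is.null(cost_rule)) {
    stop("overrides are only allowed for id = \"custom\"")
  }
  structure(sc, class = "scenario")
}

#' Run one arm comparison for a scenario and sex
#'
#' Convenience wrapper: runs control and intervention cohorts, accumulates
#' outcomes and compares them.
#'
#' @inheritParams run_cohort
#' @return List with `control`, `intervention` (`economic_outcome`) and
#'   `icer` (`icer_result`).
#' @export
run_comparison <- function(params, sex, scenario = make_scenario("base"),
                           start_age = NULL) {
  ctrl <- accumulate_outcomes(
    run_cohort(params, sex, "control", scenario, start_age), params, scenario)
  int <- accumulate_outcomes(
    run_cohort(params, sex, "intervention", scenario, start_age),
    params, scenario)
  list(control = ctrl, intervention = int,
       icer = compute_icer(int, ctrl))
}

#' Run the full published scenario suite
#'
#' Evaluates every requested scenario for every requested sex and returns
#' one comparison row per combination: control and intervention QALYs and
#' costs, incremental QALYs and costs, the ICER, and discounted life-years
#' per arm.
#'
#' @param params A `parameter_set` (start ages taken from its
#'   configuration).
#' @param sexes Character vector of sexes to run.
#' @param scenarios Character vector of scenario ids.
#' @return Data frame with one row per (scenario, sex).
#' @export
run_scenario_suite <- function(params, sexes = c("men", "women"),
                               scenarios = c("base", "s1_full_compliance",
                                             "s2_twice_yearly",
                                             "s3_utility_gain",
                                             "s4_five_year")) {
  rows <- list()
  for (sc_id in scenarios) {
    sc <- make_scenario(sc_id, params = params)
    for (sx in sexes) {
      cmp <- run_comparison(params, sx, sc)
      rows[[length(rows) + 1]] <- data.frame(
        scenario = sc_id, sex = sx,
        control_qalys = cmp$control$qalys,
        control_cost = cmp$control$costs,
        intervention_qalys = cmp$intervention$qalys,
        intervention_cost = cmp$intervention$costs,
        delta_qaly = cmp$icer$delta_qaly,
        delta_cost = cmp$icer$delta_cost,
        icer = cmp$icer$icer,
        classification = cmp$icer$classification,
        control_life_years = cmp$control$life_years,
        intervention_life_years = cmp$intervention$life_years,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Calibrate the cohort start age against published control-arm totals
#'
#' The source tables never state the modelled cohort's starting age, so it
#' is the model's one free parameter. This grid search runs the control
#' arm at every candidate age and scores each against the configured
#' calibration targets (control-arm discounted QALYs and costs) by the sum
#' of squared relative errors, returning the best age.
#'
#' @param params A `parameter_set` with `calibration_targets` in its
#'   configuration.
#' @param sex `"men"` or `"women"`.
#' @param ages Candidate integer start ages.
#' @return List with `start_age` (the winner), and `grid`, a data frame of
#'   candidate ages with their control QALYs, costs and score.
#' @export
calibrate_start_age <- function(params, sex, ages = 20:65) {
  tg <- params$config$calibration_targets[[sex]]
  if (is.null(tg)) stop("no calibration targets configured for ", sex)
  sc <- make_scenario("base", params = params)
  grid <- do.call(rbind, lapply(ages, function(a) {
    out <- accumulate_outcomes(
      run_cohort(params, sex, "control", sc, start_age = a), params, sc)
    data.frame(start_age = a, control_qalys = out$qalys,
               control_cost = out$costs)
  }))
  grid$score <- (grid$control_qalys / tg$control_qalys - 1)^2 +
    (grid$control_cost / tg$control_cost - 1)^2
  best <- grid$start_age[which.min(grid$score)]
  list(start_age = best, grid = grid)
}

#' Calibrate both sexes and return an updated parameter set
#'
#' @inheritParams calibrate_start_age
#' @return The `parameter_set` with `config$start_age` replaced by the
#'   calibrated ages (attribute `calibration` holds the grids).
#' @export
calibrate_parameters <- function(params, ages = 20:65) {
  cal <- lapply(c(men = "men", women = "women"),
                function(sx) calibrate_start_age(params, sx, ages))
  params$config$start_age <- lapply(cal, `[[`, "start_age")
  attr(params, "calibration") <- lapply(cal, `[[`, "grid")
  params
}
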