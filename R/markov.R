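#' Build the one-cycle transition matrix for a given age, sex and arm
#'
#' Constructs the 9 x 9 transition matrix over the model states for one
#' annual cycle. At-risk individuals can develop type 2 diabetes, CHD,
#' stroke or colon cancer, or die of background causes. Each published
#' incidence is multiplied by the mental-disorder relative risk (the CHD
#' relative risk switches at the configured age cutoff) and, in the
#' intervention arm, by one minus the total risk reduction implied by the
#' BMI change. Diabetic individuals additionally face a colon-cancer
#' transition (1.33 times the at-risk-to-diabetes probability before any
#' intervention effect, by default). First-year disease states are strict
#' one-cycle tunnels: occupants die with the first-year case fatality or
#' move on to the follow-up state. Case-fatality probabilities are used as
#' the total per-cycle death probability of their state; background
#' mortality is not added on top.
#'
#' @param params A `parameter_set`.
#' @param age Attained age (years) at the start of the cycle.
#' @param sex `"men"` or `"women"`.
#' @param arm `"control"` or `"intervention"`.
#' @param scenario A scenario as returned by [make_scenario()]; defaults to
#'   the base case.
#' @param reductions Optional named fractions (`diabetes`, `chd`, `stroke`,
#'   `colon`) overriding the deterministic total risk reductions; used by
#'   the probabilistic sensitivity analysis.
#' @return A 9 x 9 row-stochastic matrix with `state_names()` dimnames.
#' @export
build_transition_matrix <- function(params, age, sex,
                                    arm = c("control", "intervention"),
                                    scenario = make_scenario("base"),
                                    reductions = NULL) {
  arm <- match.arg(arm)
  e <- epi_row(params, sex, age)
  rr <- params$config$relative_risks

  if (is.null(reductions)) {
    bmi <- if (arm == "intervention") scenario$bmi_change else 0
    reductions <- vapply(c("diabetes", "chd", "stroke", "colon"),
                         function(d) total_reduction(params, d, sex, bmi),
                         numeric(1))
  } else if (arm == "control") {
    reductions <- c(diabetes = 0, chd = 0, stroke = 0, colon = 0)
  }

  # The bundled incidence table already embeds the mental-disorder relative
  # risks (it lists the transition probabilities used by the model); set
  # apply_incidence_rr to TRUE for tables of raw general-population risks.
  apply_rr <- isTRUE(params$config$options$apply_incidence_rr)
  f_dm <- if (apply_rr) rr$diabetes else 1
  f_chd <- if (!apply_rr) 1 else if (age < rr$chd_age_cutoff) rr$chd_young else rr$chd_old
  f_str <- if (apply_rr) rr$stroke else 1
  f_col <- if (apply_rr) rr$colon else 1

  p_dm  <- e[["diabetes_incidence"]] * f_dm * (1 - reductions[["diabetes"]])
  p_chd <- e[["chd_incidence"]] * f_chd * (1 - reductions[["chd"]])
  p_str <- e[["stroke_incidence"]] * f_str * (1 - reductions[["stroke"]])
  p_col <- e[["colon_incidence"]] * f_col * (1 - reductions[["colon"]])
  p_die <- e[["overall_mortality"]]

  basis <- params$config$options$diabetes_colon_basis
  p_dm_col <- if (identical(basis, "diabetes")) {
    e[["diabetes_incidence"]] * f_dm * rr$diabetes_to_colon
  } else {
    e[["colon_incidence"]] * f_col * rr$diabetes_to_colon
  }

  s <- state_names()
  m <- matrix(0, 9, 9, dimnames = list(s, s))

  set_row <- function(from, to, p) {
    total <- sum(p)
    if (total > 1 + 1e-12)
      stop(sprintf(
        "competing risks exceed probability mass 1 in state %s at age %s (%s): %.4f",
        from, format(age), sex, total))
    m[from, to] <<- p
    m[from, from] <<- m[from, from] + 1 - total
  }

  set_row("at_risk", c("diabetes", "chd_1", "stroke_1", "colon_1", "dead"),
          c(p_dm, p_chd, p_str, p_col, p_die))
  set_row("diabetes", c("colon_1", "dead"),
          c(p_dm_col, e[["diabetes_fatality"]]))
  # tunnels: leave with certainty
  m["chd_1", "dead"] <- e[["chd_fatality_year1"]]
  m["chd_1", "chd_1plus"] <- 1 - e[["chd_fatality_year1"]]
  set_row("chd_1plus", "dead", e[["chd_fatality_followup"]])
  m["stroke_1", "dead"] <- e[["stroke_fatality_year1"]]
  m["stroke_1", "stroke_1plus"] <- 1 - e[["stroke_fatality_year1"]]
  set_row("stroke_1plus", "dead", e[["stroke_fatality_followup"]])
  m["colon_1", "dead"] <- e[["colon_fatality"]]
  m["colon_1", "colon_1plus"] <- 1 - e[["colon_fatality"]]
  set_row("colon_1plus", "dead", e[["colon_fatality"]])
  m["dead", "dead"] <- 1
  m
}

#' Propagate a cohort through the model
#'
#' Places the full cohort in the at-risk state at cycle 0 and multiplies
#' the state-occupancy vector through the cycle-specific transition
#' matrices: the matrix for cycle t uses attained age `start_age + t - 1`
#' (ages beyond the top tabulated band clamp to it).
#'
#' @inheritParams build_transition_matrix
#' @param start_age Age at cycle 0; defaults to the configured start age
#'   for `sex`.
#' @param horizon Number of annual cycles; defaults to the scenario's
#'   horizon.
#' @return A `cohort_trace`: a `(horizon + 1) x 9` matrix of occupancy
#'   fractions (rows are cycles 0..horizon) with attributes `arm`, `sex`,
#'   `start_age` and `scenario_id`.
#' @export
run_cohort <- function(params, sex, arm = c("control", "intervention"),
                       scenario = make_scenario("base"),
                       start_age = NULL, horizon = NULL,
                       reductions = NULL) {
  arm <- match.arg(arm)
  if (is.null(start_age)) start_age <- params$config$start_age[[sex]]
  if (is.null(horizon)) horizon <- scenario$horizon
  stopifnot(horizon >= 0)

  occ <- matrix(0, horizon + 1, 9, dimnames = list(0:horizon, state_names()))
  occ[1, "at_risk"] <- 1
  if (horizon >= 1) {
    for (t in seq_len(horizon)) {
      m <- build_transition_matrix(params, start_age + t - 1, sex, arm,
                                   scenario, reductions)
      occ[t + 1, ] <- occ[t, ] %*% m
    }
  }
  structure(occ, class = c("cohort_trace", "matrix"),
            arm = arm, sex = sex, start_age = start_age,
            scenario_id = scenario$id)
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> %s / %s, start age %d, %d cycles\n",
              attr(x, "sex"), attr(x, "arm"), attr(x, "start_age"),
              nrow(x) - 1))
  cat(sprintf("  final occupancy: at_risk %.3f, dead %.3f\n",
              x[nrow(x), "at_risk"], x[nrow(x), "dead"]))
  invisible(x)
}

#' Export a cohort trace as a long-format data frame
#'
#' @param trace A `cohort_trace`.
#' @return Data frame with columns `cycle`, `state`, `occupancy`.
#' @export
trace_to_df <- function(trace) {
  data.frame(
    cycle = rep(0:(nrow(trace) - 1), times = 9),
    state = rep(state_names(), each = nrow(trace)),
    occupancy = as.vector(unclass(trace)[, state_names()]),
    stringsAsFactors = FALSE)
}

#' Microsimulation cross-check of the cohort engine
#'
#' Simulates `n_individuals` exchangeable individuals one state-jump at a
#' time through the same cycle-specific transition matrices used by
#' [run_cohort()], by multinomial sampling of the state counts, and
#' returns the empirical occupancy trace. With large n the empirical
#' occupancies converge to the deterministic cohort trace (binomial
#' standard error per cell), which is the validation property the test
#' suite asserts.
#'
#' @inheritParams run_cohort
#' @param n_individuals Number of simulated individuals.
#' @param seed Integer seed; the run is deterministic given the seed.
#' @return A `cohort_trace` of empirical occupancy fractions.
#' @export
microsim_oracle <- function(params, sex, arm = c("control", "intervention"),
                            scenario = make_scenario("base"),
                            n_individuals, seed,
                            start_age = NULL, horizon = NULL) {
  arm <- match.arg(arm)
  stopifnot(n_individuals >= 1)
  if (is.null(start_age)) start_age <- params$config$start_age[[sex]]
  if (is.null(horizon)) horizon <- scenario$horizon

  counts <- matrix(0L, horizon + 1, 9,
                   dimnames = list(0:horizon, state_names()))
  counts[1, "at_risk"] <- n_individuals
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (horizon >= 1) {
    for (t in seq_len(horizon)) {
      m <- build_transition_matrix(params, start_age + t - 1, sex, arm,
                                   scenario)
      nxt <- integer(9)
      for (s in which(counts[t, ] > 0)) {
        jumps <- stats::rmultinom(1, counts[t, s], m[s, ])
        nxt <- nxt + jumps[, 1]
      }
      counts[t + 1, ] <- nxt
    }
  }
  structure(counts / n_individuals, class = c("cohort_trace", "matrix"),
            arm = arm, sex = sex, start_age = start_age,
            scenario_id = scenario$id)
}
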