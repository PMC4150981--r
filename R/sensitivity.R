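#' Method-of-moments distribution fit for a sampled parameter
#'
#' Parameterises a gamma, beta or lognormal distribution so that its
#' analytic mean and standard deviation equal the supplied `(mean, se)`:
#' gamma shape `(mean/se)^2`, scale `se^2/mean`; beta with
#' `alpha + beta = mean(1-mean)/se^2 - 1`; lognormal
#' `sigma^2 = log(1 + se^2/mean^2)`, `mu = log(mean) - sigma^2/2`.
#' `se = 0` yields a degenerate point-mass sampler.
#'
#' @param family `"gamma"`, `"beta"` or `"lognormal"`.
#' @param mean Target mean (positive; inside (0, 1) for beta).
#' @param se Target standard deviation (>= 0).
#' @return List with `family`, the fitted `params`, and `r`, a `function(n)`
#'   drawing n variates.
#' @export
fit_distribution <- function(family = c("gamma", "beta", "lognormal"),
                             mean, se) {
  family <- match.arg(family)
  stopifnot(se >= 0)
  if (se == 0) {
    return(list(family = family, params = list(mean = mean),
                r = function(n) rep(mean, n)))
  }
  switch(family,
    gamma = {
      stopifnot(mean > 0)
      shape <- (mean / se)^2
      scale <- se^2 / mean
      list(family = family, params = list(shape = shape, scale = scale),
           r = function(n) stats::rgamma(n, shape = shape, scale = scale))
    },
    beta = {
      stopifnot(mean > 0, mean < 1)
      if (se^2 >= mean * (1 - mean))
        stop(sprintf(
          "beta distribution infeasible: se^2 = %.4g >= mean(1-mean) = %.4g",
          se^2, mean * (1 - mean)))
      nu <- mean * (1 - mean) / se^2 - 1
      alpha <- mean * nu
      beta <- (1 - mean) * nu
      list(family = family, params = list(alpha = alpha, beta = beta),
           r = function(n) stats::rbeta(n, alpha, beta))
    },
    lognormal = {
      stopifnot(mean > 0)
      sigma2 <- log(1 + se^2 / mean^2)
      mu <- log(mean) - sigma2 / 2
      list(family = family, params = list(mu = mu, sigma = sqrt(sigma2)),
           r = function(n) stats::rlnorm(n, mu, sqrt(sigma2)))
    })
}

# Canonical one-way parameter names.
one_way_parameters <- function() {
  c("intervention_effect", "intervention_cost",
    "cost_diabetes", "cost_chd_year1", "cost_chd_followup",
    "cost_stroke_year1", "cost_stroke_followup", "cost_colon",
    "rr_reduction_diabetes", "rr_reduction_chd", "rr_reduction_stroke",
    "rr_reduction_colon")
}

# Return params with the named parameter scaled by `factor` (for the given
# sex where the parameter is sex-specific).
scale_parameter <- function(params, parameter, factor, sex) {
  p <- params
  if (parameter == "intervention_effect") {
    p$config$bmi_change <- p$config$bmi_change * factor
  } else if (parameter == "intervention_cost") {
    comp <- p$config$intervention_components_eur
    p$config$intervention_components_eur <- lapply(comp, function(x) x * factor)
  } else if (startsWith(parameter, "cost_")) {
    item <- sub("^cost_", "", parameter)
    items <- if (item == "colon") c("colon_year1", "colon_followup") else item
    hit <- p$costs$item %in% items
    if (!any(hit)) stop("unknown parameter name: ", parameter)
    p$costs$annual_cost_eur[hit] <- p$costs$annual_cost_eur[hit] * factor
  } else if (startsWith(parameter, "rr_reduction_")) {
    disease <- sub("^rr_reduction_", "", parameter)
    hit <- p$effects$disease == disease & p$effects$sex == sex
    if (!any(hit)) stop("unknown parameter name: ", parameter)
    p$effects$per_unit_reduction_pct[hit] <-
      p$effects$per_unit_reduction_pct[hit] * factor
    p$effects$per_unit_reduction[hit] <-
      p$effects$per_unit_reduction[hit] * factor
    p$effects$rr_reduction_pct[hit] <-
      p$effects$per_unit_reduction_pct[hit] * 0.20
  } else {
    stop("unknown parameter name: ", parameter)
  }
  p
}

#' One-way sensitivity analysis of a single parameter
#'
#' Reruns the full deterministic comparison twice with the named parameter
#' scaled to 70% and 130% of its base value (all other inputs untouched)
#' and records the two ICERs. Note the scenario's BMI change tracks the
#' configured value when `intervention_effect` is scaled.
#'
#' @param params A `parameter_set`.
#' @param parameter One of [one_way_parameters()].
#' @param scenario Scenario to evaluate under.
#' @param sex `"men"` or `"women"`.
#' @param factors Length-2 scaling factors (default `c(0.7, 1.3)`).
#' @return A one-row data frame: `parameter`, `icer_low`, `icer_high`,
#'   `range` (absolute width).
#' @export
one_way <- function(params, parameter, scenario = make_scenario("base"),
                    sex = "men", factors = c(0.7, 1.3)) {
  icers <- vapply(factors, function(f) {
    p <- scale_parameter(params, parameter, f, sex)
    # rebuild the scenario so a scaled intervention effect propagates
    sc <- scenario
    if (parameter == "intervention_effect" &&
        scenario$id %in% c("base", "s2_twice_yearly", "s3_utility_gain",
                           "s4_five_year"))
      sc$bmi_change <- p$config$bmi_change
    if (parameter == "intervention_effect" && scenario$id == "s1_full_compliance")
      sc$bmi_change <- scenario$bmi_change * f
    run_comparison(p, sex, sc)$icer$icer
  }, numeric(1))
  data.frame(parameter = parameter, icer_low = icers[1], icer_high = icers[2],
             range = abs(icers[2] - icers[1]), stringsAsFactors = FALSE)
}

#' Tornado analysis: one-way results for every key parameter
#'
#' Runs [one_way()] for the intervention effect, the intervention cost,
#' every disease cost and every BMI-related risk reduction, and orders the
#' results by decreasing ICER range, ready for a tornado plot.
#'
#' @inheritParams one_way
#' @param parameters Parameter names (default: all of
#'   [one_way_parameters()]).
#' @return Data frame of one-way results sorted by descending `range`,
#'   with the base-case ICER in the `icer_base` column.
#' @export
tornado <- function(params, scenario = make_scenario("base"), sex = "men",
                    parameters = one_way_parameters(),
                    factors = c(0.7, 1.3)) {
  stopifnot(length(parameters) >= 1)
  base_icer <- run_comparison(params, sex, scenario)$icer$icer
  res <- do.call(rbind, lapply(parameters, function(pn)
    one_way(params, pn, scenario, sex, factors)))
  res$icer_base <- base_icer
  res[order(-res$range), ]
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets with every published mean/SE pair sampled from
#' its assigned family (costs and programme costs gamma, utilities beta,
#' total risk reductions lognormal; method-of-moments fits), reruns both
#' arms for each draw, and summarises the incremental results. Draw order
#' is fixed (risk reductions, then costs, then utilities, each in table
#' order, all draws per parameter at once), so a given seed is
#' reproducible across machines. Draws whose transition rows would exceed
#' probability mass 1 are rejected and redrawn (count reported).
#'
#' The summary ICER is reported three ways: as the ratio of mean
#' incremental cost to mean incremental QALYs (the headline `mean_icer`),
#' as the median of per-draw ratios, and as the raw mean of per-draw
#' ratios (excluding draws with |delta QALY| < 1e-9). The raw mean is kept
#' only as a diagnostic: the per-draw ratio has no finite expectation
#' (draws with near-zero incremental QALYs produce arbitrarily large
#' ratios of either sign), so its sample mean does not converge.
#'
#' @inheritParams one_way
#' @param n Number of draws (>= 2).
#' @param seed Integer seed.
#' @param threshold Willingness-to-pay threshold (euro/QALY) for the
#'   cost-effectiveness plane summary.
#' @return A `psa_result`: per-draw data frame (`delta_qaly`, `delta_cost`,
#'   `icer`), means, 95% percentile credible intervals, the two mean-ICER
#'   variants, the fraction of draws cost-effective at the threshold, and
#'   bookkeeping counts.
#' @export
run_psa <- function(params, scenario = make_scenario("base"), sex = "men",
                    n = 10000, seed = 1,
                    threshold = params$config$threshold_eur_per_qaly) {
  stopifnot(n >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  start_age <- params$config$start_age[[sex]]
  horizon <- scenario$horizon
  eff <- params$effects[params$effects$sex == sex, ]
  se_scale <- if (identical(params$config$options$rr_reduction_se_scale,
                            "fraction")) 100 else 1

  # --- draw all sampled parameters (fixed order) ---------------------------
  red_draws <- sapply(c("diabetes", "chd", "stroke", "colon"), function(d) {
    row <- eff[eff$disease == d, ]
    mean_pct <- row$per_unit_reduction_pct * scenario$bmi_change
    fit_distribution("lognormal", mean_pct, row$se_pct * se_scale)$r(n) / 100
  })
  cost_items <- c("diabetes", "chd_year1", "chd_followup", "stroke_year1",
                  "stroke_followup", "colon_year1", "colon_followup",
                  "intervention_pedometer_year", "intervention_other_year")
  cost_draws <- sapply(cost_items, function(it) {
    row <- params$costs[params$costs$item == it, ]
    fit_distribution("gamma", row$annual_cost_eur, row$se_eur)$r(n)
  })
  util_states <- setdiff(state_names(), "dead")
  util_draws <- sapply(util_states, function(st) {
    row <- params$utilities[params$utilities$state == st, ]
    fit_distribution("beta", row$utility, row$se)$r(n)
  })

  # --- deterministic pieces shared across draws ----------------------------
  ctrl_trace <- run_cohort(params, sex, "control", scenario,
                           start_age = start_age, horizon = horizon)
  ctrl_mats <- lapply(seq_len(horizon), function(t)
    build_transition_matrix(params, start_age + t - 1, sex, "control",
                            scenario))
  disease_cols <- match(c("diabetes", "chd_1", "stroke_1", "colon_1"),
                        state_names())

  cfg <- params$config
  both_ends <- !identical(cfg$options$accumulation, "transitions_only")
  if (both_ends) { idx <- seq_len(horizon + 1); expo <- 0:horizon
  } else { idx <- seq_len(horizon) + 1; expo <- 0:(horizon - 1) }
  dq <- (1 + cfg$discount$qaly)^(-expo)
  dc <- (1 + cfg$discount$cost)^(-expo)
  life <- cfg$pedometer_life_years
  ped_year <- ((seq_len(horizon) - 1) %% life) == 0
  sched_disc <- dc[seq_len(horizon)]   # year y at cycle y-1 in both conventions

  occ_weights <- function(trace) {
    occ <- unclass(trace)[, state_names(), drop = FALSE]
    list(q = colSums(occ[idx, , drop = FALSE] * dq),
         c = colSums(occ[idx, , drop = FALSE] * dc),
         alive = 1 - occ[, "dead"])
  }
  wc <- occ_weights(ctrl_trace)

  state_u <- function(u_named, gain) {
    u <- c(u_named, dead = 0)[state_names()]
    if (gain > 0) u[["at_risk"]] <- min(1, u[["at_risk"]] + gain)
    u
  }
  gain <- if (isTRUE(scenario$utility_gain))
    cfg$utility_gain_per_bmi_unit * scenario$bmi_change else 0

  n_rejected <- 0L
  dqaly <- dcost <- numeric(n)
  for (i in seq_len(n)) {
    red <- red_draws[i, ]
    # reject-and-redraw if the reduced at-risk row could exceed mass 1
    repeat {
      if (all(red <= 1)) break
      n_rejected <- n_rejected + 1L
      red <- sapply(c("diabetes", "chd", "stroke", "colon"), function(d) {
        row <- eff[eff$disease == d, ]
        mean_pct <- row$per_unit_reduction_pct * scenario$bmi_change
        fit_distribution("lognormal", mean_pct,
                         row$se_pct * se_scale)$r(1) / 100
      })
    }
    # intervention trace: control matrices with the at-risk row rescaled
    v <- c(1, numeric(8))
    occ_i <- matrix(0, horizon + 1, 9)
    occ_i[1, ] <- v
    for (t in seq_len(horizon)) {
      m <- ctrl_mats[[t]]
      row1 <- m[1, ]
      row1[disease_cols] <- row1[disease_cols] *
        (1 - red[c("diabetes", "chd", "stroke", "colon")])
      row1[1] <- 1 - sum(row1[-1])
      m[1, ] <- row1
      v <- v %*% m
      occ_i[t + 1, ] <- v
    }
    wi <- list(q = colSums(occ_i[idx, , drop = FALSE] * dq),
               c = colSums(occ_i[idx, , drop = FALSE] * dc),
               alive = 1 - occ_i[, 9])

    u_ctrl <- state_u(util_draws[i, ], 0)
    u_int <- state_u(util_draws[i, ], gain)
    costs <- cost_draws[i, ]
    cvec <- c(at_risk = 0, diabetes = costs[["diabetes"]],
              chd_1 = costs[["chd_year1"]], chd_1plus = costs[["chd_followup"]],
              stroke_1 = costs[["stroke_year1"]],
              stroke_1plus = costs[["stroke_followup"]],
              colon_1 = costs[["colon_year1"]],
              colon_1plus = costs[["colon_followup"]], dead = 0)
    sched <- ifelse(ped_year, costs[["intervention_pedometer_year"]],
                    costs[["intervention_other_year"]])
    if (identical(scenario$cost_rule, "twice_yearly")) {
      comp <- cfg$intervention_components_eur
      base_oth <- comp$staff + comp$admin + comp$manual
      extra <- if (identical(cfg$options$s2_rule, "double_all"))
        sched else base_oth
      sched <- sched + extra
    }
    weight <- if (identical(cfg$options$charge_intervention_to, "at_risk")) {
      occ_i[seq_len(horizon), 1]
    } else wi$alive[seq_len(horizon)]
    prog <- sum(sched * weight * sched_disc)

    dqaly[i] <- sum(wi$q * u_int) - sum(wc$q * u_ctrl)
    dcost[i] <- (sum(wi$c * cvec) + prog) - sum(wc$c * cvec)
  }

  icer <- ifelse(abs(dqaly) < 1e-9, NA_real_, dcost / dqaly)
  kept <- !is.na(icer)
  ci <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  structure(list(
    n = n,
    draws = data.frame(delta_qaly = dqaly, delta_cost = dcost, icer = icer),
    mean_delta_qaly = mean(dqaly),
    mean_delta_cost = mean(dcost),
    ci_delta_qaly = ci(dqaly),
    ci_delta_cost = ci(dcost),
    mean_icer = mean(dcost) / mean(dqaly),
    icer_median = stats::median(icer[kept]),
    icer_mean_of_ratios = mean(icer[kept]),
    ci_icer = ci(icer[kept]),
    frac_cost_effective = mean(dcost < threshold * dqaly),
    threshold = threshold,
    n_excluded_icer = sum(!kept),
    n_rejected = n_rejected,
    sex = sex, scenario_id = scenario$id, seed = seed),
    class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %s, scenario %s, %d draws (seed %d)\n",
              x$sex, x$scenario_id, x$n, x$seed))
  cat(sprintf("  mean dQALY %.4f (95%% CI %.4f-%.4f)\n",
              x$mean_delta_qaly, x$ci_delta_qaly[1], x$ci_delta_qaly[2]))
  cat(sprintf("  mean dCost %.0f EUR (95%% CI %.0f-%.0f)\n",
              x$mean_delta_cost, x$ci_delta_cost[1], x$ci_delta_cost[2]))
  cat(sprintf("  mean ICER %.0f EUR/QALY (per-draw 95%% CI %.0f-%.0f, median %.0f)\n",
              x$mean_icer, x$ci_icer[1], x$ci_icer[2], x$icer_median))
  cat(sprintf("  cost-effective at %.0f EUR/QALY: %.1f%% of draws\n",
              x$threshold, 100 * x$frac_cost_effective))
  invisible(x)
}

#' Cost-effectiveness-plane points from a PSA
#'
#' @param psa A `psa_result`.
#' @return Data frame with `delta_qaly` (incremental effectiveness, x),
#'   `delta_cost` (y) and `below_threshold` (logical: cheaper than the
#'   willingness-to-pay line `delta_cost = threshold x delta_qaly`).
#' @export
ce_plane <- function(psa) {
  data.frame(delta_qaly = psa$draws$delta_qaly,
             delta_cost = psa$draws$delta_cost,
             below_threshold = psa$draws$delta_cost <
               psa$threshold * psa$draws$delta_qaly)
}
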