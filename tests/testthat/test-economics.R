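static_trace <- function(horizon, arm = "control", sex = "men",
                         start_age = 45) {
  occ <- matrix(0, horizon + 1, 9, dimnames = list(0:horizon, state_names()))
  occ[, "at_risk"] <- 1
  structure(occ, class = c("cohort_trace", "matrix"), arm = arm, sex = sex,
            start_age = start_age, scenario_id = "custom")
}

test_that("discount factors follow the first-year-undiscounted convention", {
  expect_equal(discount_factor(0.03, 1), 1.0)
  expect_equal(discount_factor(0.03, 2), 1 / 1.03)
  expect_equal(discount_factor(0.03, 2), 0.970874, tolerance = 1e-6)
  expect_equal(discount_factor(0, 17), 1.0)
  expect_equal(discount_factor(0.03, 3, convention = "end_year"), 1.03^-3)
})

test_that("the programme cost schedule charges a pedometer every five years", {
  p <- paper_params()
  sched <- intervention_cost_schedule(p, 20)
  expect_equal(sched[c(1, 6, 11, 16)], rep(35.00, 4))
  expect_equal(sched[setdiff(1:20, c(1, 6, 11, 16))], rep(21.30, 16))
  expect_equal(intervention_cost_schedule(p, 5), c(35, rep(21.30, 4)))
  # twice-yearly programme: staff/admin/manual double, the pedometer is durable
  s2 <- make_scenario("s2")
  expect_equal(intervention_cost_schedule(p, 20, s2)[1:7],
               c(56.30, 42.60, 42.60, 42.60, 42.60, 56.30, 42.60))
})

test_that("QALY accumulation matches closed forms for a static cohort", {
  p <- paper_params()
  # published convention: value both endpoints, cycle t at (1+r)^-t
  out <- accumulate_outcomes(static_trace(2), p)
  expect_equal(out$qalys, 0.71 * (1 + 1 / 1.015 + 1 / 1.015^2))
  expect_equal(out$life_years, 1 + 1 / 1.015 + 1 / 1.015^2)
  expect_equal(out$costs, 0)

  # alternative convention: cycles 1..H, first year undiscounted
  p2 <- p
  p2$config$options$accumulation <- "transitions_only"
  out2 <- accumulate_outcomes(static_trace(2), p2)
  expect_equal(out2$qalys, 0.71 * (1 + 1 / 1.015))
  expect_equal(out2$qalys, 1.40951, tolerance = 1e-5)
})

test_that("an extinct cohort accrues nothing", {
  occ <- matrix(0, 4, 9, dimnames = list(0:3, state_names()))
  occ[, "dead"] <- 1
  tr <- structure(occ, class = c("cohort_trace", "matrix"), arm = "control",
                  sex = "men", start_age = 45, scenario_id = "custom")
  out <- accumulate_outcomes(tr, paper_params())
  expect_equal(out$qalys, 0)
  expect_equal(out$costs, 0)
  expect_equal(out$life_years, 0)
})

test_that("zero discount rates collapse discounted onto undiscounted outcomes", {
  p <- paper_params()
  p$config$discount$cost <- 0
  p$config$discount$qaly <- 0
  tr <- run_cohort(p, "women", "intervention")
  out <- accumulate_outcomes(tr, p)
  expect_equal(out$qalys, out$qalys_undiscounted)
  expect_equal(out$costs, out$costs_undiscounted)
  expect_equal(out$life_years, out$life_years_undiscounted)
  # and with the published rates, discounting can only shrink totals
  out2 <- accumulate_outcomes(run_cohort(paper_params(), "women", "intervention"),
                              paper_params())
  expect_lt(out2$qalys, out2$qalys_undiscounted)
  expect_lt(out2$costs, out2$costs_undiscounted)
  expect_lte(out2$qalys, out2$life_years)
})

test_that("outcomes are monotone in state utilities and costs", {
  p <- paper_params()
  tr <- run_cohort(p, "men", "control")
  base <- accumulate_outcomes(tr, p)
  up <- p
  up$utilities$utility[up$utilities$state == "stroke_1plus"] <- 0.60
  expect_gt(accumulate_outcomes(tr, up)$qalys, base$qalys)
  upc <- p
  upc$costs$annual_cost_eur[upc$costs$item == "diabetes"] <- 4000
  expect_gt(accumulate_outcomes(tr, upc)$costs, base$costs)
})

test_that("ICERs follow the incremental-ratio definition with dominance labels", {
  p <- paper_params()
  tr <- run_cohort(p, "men", "control")
  out <- accumulate_outcomes(tr, p)
  mk <- function(dq, dc) {
    x <- out
    x$qalys <- out$qalys + dq
    x$costs <- out$costs + dc
    x$arm <- "intervention"
    x
  }
  r <- compute_icer(mk(0.01, 100), out)
  expect_equal(r$icer, 10000)
  expect_equal(r$classification, "ratio")
  expect_equal(compute_icer(mk(0, 0), out)$classification, "indeterminate")
  expect_true(is.na(compute_icer(mk(0, 50), out)$icer))
  expect_equal(compute_icer(mk(0.01, -5), out)$classification, "dominant")
  expect_equal(compute_icer(mk(-0.01, 5), out)$classification, "dominated")

  other <- accumulate_outcomes(run_cohort(p, "women", "control"), p)
  expect_error(compute_icer(mk(0.01, 100), other), "mismatched")
})

test_that("zero effect at zero programme cost gives exactly zero increments", {
  p <- paper_params()
  p$config$intervention_components_eur <-
    list(pedometer = 0, staff = 0, admin = 0, manual = 0)
  sc <- make_scenario("custom", bmi_change = 0)
  cmp <- run_comparison(p, "men", sc)
  expect_identical(cmp$icer$delta_qaly, 0)
  expect_identical(cmp$icer$delta_cost, 0)
  expect_equal(cmp$icer$classification, "indeterminate")
})

test_that("reported ICERs are internally consistent with their increments", {
  p <- paper_params()
  suite <- run_scenario_suite(p)
  expect_equal(suite$icer, suite$delta_cost / suite$delta_qaly)
})
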