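test_that("transition probabilities compose incidence, relative risk and effect", {
  # with a raw general-population table the mental-disorder RR is applied
  # at run time: men 20-24 diabetes 0.06% x 1.77
  p_rr <- rr_applied_params()
  m <- build_transition_matrix(p_rr, 22, "men", "control")
  expect_equal(m["at_risk", "diabetes"], 0.0006 * 1.77)
  mi <- build_transition_matrix(p_rr, 22, "men", "intervention")
  expect_equal(mi["at_risk", "diabetes"], 0.0006 * 1.77 * (1 - 0.0260))
  # the CHD relative risk switches at the age cutoff
  m49 <- build_transition_matrix(p_rr, 49, "men", "control")
  m50 <- build_transition_matrix(p_rr, 50, "men", "control")
  expect_equal(m49["at_risk", "chd_1"], 0.0035 * 1.42)
  expect_equal(m50["at_risk", "chd_1"], 0.0041 * 1.01)

  # bundled table: probabilities are used as printed
  p <- paper_params()
  m <- build_transition_matrix(p, 22, "men", "control")
  expect_equal(m["at_risk", "diabetes"], 0.0006)
  mi <- build_transition_matrix(p, 22, "men", "intervention")
  expect_equal(mi["at_risk", "diabetes"], 0.0006 * (1 - 0.0260))
  # diabetes -> colon cancer: at-risk -> colon probability x 1.33
  expect_equal(m["diabetes", "colon_1"], 0.0001 * 1.33)
  p2 <- p
  p2$config$options$diabetes_colon_basis <- "diabetes"
  m2 <- build_transition_matrix(p2, 22, "men", "control")
  expect_equal(m2["diabetes", "colon_1"], 0.0006 * 1.33)
})

test_that("zero incidence and mortality freeze every non-tunnel state", {
  m <- build_transition_matrix(zeroed_params(), 40, "women", "intervention")
  frozen <- c("at_risk", "diabetes", "chd_1plus", "stroke_1plus",
              "colon_1plus", "dead")
  for (s in frozen) expect_equal(m[s, s], 1)
  # first-year states remain one-cycle tunnels even without fatalities
  expect_equal(m["chd_1", "chd_1plus"], 1)
  expect_equal(m["stroke_1", "stroke_1plus"], 1)
  expect_equal(m["colon_1", "colon_1plus"], 1)
  expect_true(all(abs(rowSums(m) - 1) < 1e-12))
})

test_that("matrices are row-stochastic with the permitted-transition pattern", {
  p <- paper_params()
  s <- state_names()
  # structurally allowed entries (including self-transitions)
  allowed <- rbind(
    cbind("at_risk", c("at_risk", "diabetes", "chd_1", "stroke_1", "colon_1", "dead")),
    cbind("diabetes", c("diabetes", "colon_1", "dead")),
    cbind("chd_1", c("chd_1plus", "dead")),
    cbind("chd_1plus", c("chd_1plus", "dead")),
    cbind("stroke_1", c("stroke_1plus", "dead")),
    cbind("stroke_1plus", c("stroke_1plus", "dead")),
    cbind("colon_1", c("colon_1plus", "dead")),
    cbind("colon_1plus", c("colon_1plus", "dead")),
    cbind("dead", "dead"))
  mask <- matrix(FALSE, 9, 9, dimnames = list(s, s))
  mask[allowed] <- TRUE
  for (sx in c("men", "women")) for (arm in c("control", "intervention"))
    for (age in c(20, 33, 47, 58, 64, 90)) {
      m <- build_transition_matrix(p, age, sx, arm)
      expect_true(all(abs(rowSums(m) - 1) < 1e-12))
      expect_true(all(m >= 0 & m <= 1))
      expect_true(all(m[!mask] == 0))
      expect_equal(m["chd_1", "chd_1"], 0)   # first year is a one-cycle tunnel
      expect_equal(unname(m["dead", ]), c(rep(0, 8), 1))
    }
})

test_that("a row whose competing risks exceed probability 1 aborts", {
  p <- paper_params()
  p$epidemiology$diabetes_incidence <- 0.7
  p$epidemiology$stroke_incidence <- 0.7
  expect_error(build_transition_matrix(p, 40, "men", "control"),
               "probability mass")
})

test_that("cohort traces start at risk and satisfy occupancy invariants", {
  p <- paper_params()
  tr0 <- run_cohort(p, "men", "control", horizon = 0)
  expect_equal(nrow(tr0), 1L)
  expect_equal(tr0[1, "at_risk"], 1)

  for (arm in c("control", "intervention")) {
    tr <- run_cohort(p, "women", arm)
    expect_equal(nrow(tr), 21L)
    expect_true(all(abs(rowSums(tr) - 1) < 1e-10))
    expect_true(all(diff(tr[, "dead"]) >= 0))
    expect_true(all(diff(tr[, "at_risk"]) <= 0))
  }

  # one cycle from age 45: deaths are the background mortality 0.24%
  tr1 <- run_cohort(p, "men", "control", start_age = 45, horizon = 1)
  expect_equal(tr1[2, "dead"], 0.0024)
})

test_that("the intervention weakly reduces disease inflow, monotonically in effect", {
  p <- paper_params()
  for (age in c(25, 47, 62)) {
    mc <- build_transition_matrix(p, age, "men", "control")
    mi <- build_transition_matrix(p, age, "men", "intervention")
    dis <- c("diabetes", "chd_1", "stroke_1", "colon_1")
    expect_true(all(mi["at_risk", dis] <= mc["at_risk", dis]))
    expect_true(all(mi["at_risk", dis] < mc["at_risk", dis]))
  }

  # BMI change 0 -> 0.20 -> 0.33: cumulative disease incidence weakly
  # decreases and QALYs weakly increase
  prev <- NULL
  for (bmi in c(0, 0.20, 0.33)) {
    sc <- make_scenario("custom", bmi_change = bmi)
    tr <- run_cohort(p, "men", "intervention", sc)
    out <- accumulate_outcomes(tr, p, sc)
    cum_disease <- sum(tr[21, c("diabetes", "chd_1plus", "stroke_1plus",
                                "colon_1plus")])
    if (!is.null(prev)) {
      expect_lte(cum_disease, prev$cum)
      expect_gte(out$qalys, prev$q)
    }
    prev <- list(cum = cum_disease, q = out$qalys)
  }

  # zero effect: the two arms are identical
  sc0 <- make_scenario("custom", bmi_change = 0)
  expect_identical(run_cohort(p, "men", "intervention", sc0)[, ],
                   run_cohort(p, "men", "control", sc0)[, ])
})

test_that("the microsimulation reproduces the cohort trace", {
  p <- paper_params()
  # degenerate case: no transitions possible
  tr <- microsim_oracle(zeroed_params(), "men", "control",
                        n_individuals = 1, seed = 11)
  expect_true(all(tr[, "at_risk"] == 1))

  # determinism: same seed, identical trace
  a <- microsim_oracle(p, "women", "intervention", n_individuals = 2000, seed = 5)
  b <- microsim_oracle(p, "women", "intervention", n_individuals = 2000, seed = 5)
  expect_identical(a[, ], b[, ])

  # convergence at moderate n: binomial-scale agreement per cell
  n <- 20000
  emp <- microsim_oracle(p, "men", "control", n_individuals = n, seed = 3)
  coh <- run_cohort(p, "men", "control")
  se <- sqrt(unclass(coh) * (1 - unclass(coh)) / n)
  dev <- abs(unclass(emp) - unclass(coh))
  live <- se > 0
  z <- dev[live] / se[live]
  expect_true(mean(z <= 3) >= 0.99)
  expect_true(all(z < 4.5))
  expect_true(all(dev[!live] == 0))
})

test_that("a cohort trace exports to long format", {
  tr <- run_cohort(paper_params(), "men", "control", horizon = 3)
  df <- trace_to_df(tr)
  expect_equal(nrow(df), 4 * 9)
  expect_equal(sum(df$occupancy[df$cycle == 2]), 1)
})
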