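# Shared fixtures: load the bundled parameter set once per test run.
.fixture_cache <- new.env(parent = emptyenv())

paper_params <- function() {
  if (is.null(.fixture_cache$p)) .fixture_cache$p <- default_parameters()
  .fixture_cache$p
}

# Parameter set with every incidence and mortality zeroed: the cohort
# never leaves the at-risk state.
zeroed_params <- function() {
  p <- paper_params()
  for (q in epi_quantities_public()) p$epidemiology[[q]] <- 0
  p
}

# epi_quantities() is internal; recreate the column list from the table.
epi_quantities_public <- function() {
  setdiff(names(paper_params()$epidemiology),
          c("sex", "age_lower", "age_upper"))
}

# Parameter set configured for tables of raw general-population risks,
# to which the mental-disorder relative risks are applied at run time.
rr_applied_params <- function() {
  p <- paper_params()
  p$config$options$apply_incidence_rr <- TRUE
  p
}

expect_within <- function(value, target, rel_tol) {
  expect_lt(abs(value / target - 1), rel_tol)
}
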