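#' The bundled published parameterisation
#'
#' Loads the parameter bundle shipped with the package: the age- and
#' sex-specific incidence, case-fatality and mortality table, the
#' BMI-related risk reductions, the state costs and programme costs, the
#' state utilities, and the run configuration (discount rates, relative
#' risks, calibrated start ages).
#'
#' @return A validated `parameter_set`.
#' @export
default_parameters <- function() {
  load_parameters(system.file("extdata", package = "lifestyleCEA"))
}

#' Write the bundled parameter tables to a directory
#'
#' Emits the published tables as machine-readable CSV/YAML files (percent
#' scale, printed precision) so a run can be audited or modified outside
#' the package. Reloading the written bundle is value-identical to the
#' bundled set.
#'
#' @param outdir Output directory (created if absent).
#' @return The loaded-back `parameter_set`, invisibly.
#' @export
write_paper_fixture <- function(outdir) {
  write_parameters(default_parameters(), outdir)
  invisible(load_parameters(outdir))
}

#' Generate a random valid perturbation of the bundled parameters
#'
#' Multiplies every epidemiological probability, risk reduction, cost,
#' utility and SE by an independent uniform factor in
#' `[1 - magnitude, 1 + magnitude]`, then repairs the result so that every
#' structural invariant still holds (probabilities clipped to [0, 1],
#' utilities to [0, 1], dead kept at 0, beta SEs kept feasible). Intended
#' as a property-test input generator: any returned set passes
#' [validate_parameters()] and runs end-to-end.
#'
#' @param seed Integer seed; same seed, same parameter set.
#' @param magnitude Relative perturbation half-width in [0, 0.5].
#' @param base Parameter set to perturb (default: the bundled one).
#' @return A validated `parameter_set`.
#' @export
perturbed_parameters <- function(seed, magnitude = 0.2,
                                 base = default_parameters()) {
  stopifnot(magnitude >= 0, magnitude <= 0.5)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  p <- base
  jitter <- function(x, lo = 0, hi = Inf) {
    f <- stats::runif(length(x), 1 - magnitude, 1 + magnitude)
    pmin(pmax(x * f, lo), hi)
  }
  for (q in epi_quantities())
    p$epidemiology[[q]] <- jitter(p$epidemiology[[q]], 0, 1)
  p$effects$per_unit_reduction_pct <-
    jitter(p$effects$per_unit_reduction_pct, 0, 100)
  p$effects$per_unit_reduction <- p$effects$per_unit_reduction_pct / 100
  p$effects$rr_reduction_pct <- p$effects$per_unit_reduction_pct * 0.20
  p$effects$se_pct <- jitter(p$effects$se_pct, 0)
  p$effects$se_chr <- format(p$effects$se_pct)
  p$costs$annual_cost_eur <- jitter(p$costs$annual_cost_eur, 0)
  p$costs$se_eur <- jitter(p$costs$se_eur, 0)
  alive <- p$utilities$state != "dead"
  p$utilities$utility[alive] <- jitter(p$utilities$utility[alive], 0, 1)
  p$utilities$se[alive] <- jitter(p$utilities$se[alive], 0)
  # keep beta parameterisations feasible: SE^2 < u(1-u)
  cap <- sqrt(pmax(p$utilities$utility * (1 - p$utilities$utility), 0)) * 0.9
  p$utilities$se <- pmin(p$utilities$se, cap)
  report <- validate_parameters(p)
  if (nrow(report))
    stop("internal error: perturbed parameters failed validation:\n",
         paste(report$message, collapse = "\n"))
  p
}
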