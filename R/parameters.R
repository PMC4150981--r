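#' Names of the nine model health states
#'
#' The cohort model distinguishes a disease-free "at risk" state, type 2
#' diabetes, first-year and subsequent-year states for coronary heart
#' disease (CHD), stroke and colon cancer, and an absorbing dead state.
#' The first-year states are tunnel states: occupants stay for exactly one
#' cycle and then either die or move to the matching follow-up state.
#'
#' @return Character vector of length 9, in the canonical state order used
#'   by all transition matrices and cohort traces.
#' @export
state_names <- function() {
  c("at_risk", "diabetes", "chd_1", "chd_1plus",
    "stroke_1", "stroke_1plus", "colon_1", "colon_1plus", "dead")
}

# Epidemiology quantities carried per sex and 5-year age band (annual
# probabilities, stored internally as fractions).
epi_quantities <- function() {
  c("diabetes_incidence", "diabetes_fatality",
    "chd_incidence", "chd_fatality_year1", "chd_fatality_followup",
    "stroke_incidence", "stroke_fatality_year1", "stroke_fatality_followup",
    "colon_incidence", "colon_fatality", "overall_mortality")
}

#' Load a model parameter set from a fixture directory
#'
#' Reads the four CSV tables (`epidemiology.csv`, `effects.csv`,
#' `costs.csv`, `utilities.csv`) and the `run_config.yaml` run
#' configuration from `path`. Probabilities and risk reductions are stored
#' in the files as percentages, exactly as published, and converted to
#' fractions here. The returned set is validated; any violation aborts the
#' load with a message naming the offending field.
#'
#' @param path Directory containing the parameter files.
#' @return A `parameter_set` object (see [default_parameters()] for the
#'   bundled parameterisation).
#' @export
load_parameters <- function(path) {
  stopifnot(dir.exists(path))
  need <- c("epidemiology.csv", "effects.csv", "costs.csv",
            "utilities.csv", "run_config.yaml")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("parameter bundle is missing file(s): ", paste(missing, collapse = ", "))

  epi <- utils::read.csv(file.path(path, "epidemiology.csv"),
                         stringsAsFactors = FALSE)
  eff <- utils::read.csv(file.path(path, "effects.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = c(se_pct = "character"))
  cost <- utils::read.csv(file.path(path, "costs.csv"),
                          stringsAsFactors = FALSE)
  util <- utils::read.csv(file.path(path, "utilities.csv"),
                          stringsAsFactors = FALSE)
  config <- yaml::read_yaml(file.path(path, "run_config.yaml"))

  for (q in epi_quantities()) {
    if (!q %in% names(epi)) stop("epidemiology.csv lacks column: ", q)
    epi[[q]] <- epi[[q]] / 100
  }
  eff$se_chr <- eff$se_pct          # printed form, kept for round-tripping
  eff$se_pct <- as.numeric(eff$se_pct)
  eff$per_unit_reduction <- eff$per_unit_reduction_pct / 100

  params <- structure(
    list(epidemiology = epi, effects = eff, costs = cost,
         utilities = util, config = config),
    class = "parameter_set")
  report <- validate_parameters(params)
  if (nrow(report))
    stop("invalid parameter set:\n",
         paste(sprintf("  %s: %s", report$field, report$message),
               collapse = "\n"))
  params
}

#' Write a parameter set back to fixture files
#'
#' Inverse of [load_parameters()]: emits the four CSV tables (percent
#' scale, two printed decimals for probabilities) and the YAML run
#' configuration into `path`, so that reloading is value-identical.
#'
#' @param params A `parameter_set`.
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "parameter_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  epi <- params$epidemiology
  for (q in epi_quantities()) epi[[q]] <- sprintf("%.2f", epi[[q]] * 100)
  utils::write.csv(epi, file.path(path, "epidemiology.csv"),
                   row.names = FALSE, quote = FALSE)
  eff <- params$effects
  eff <- data.frame(disease = eff$disease, sex = eff$sex,
                    per_unit_reduction_pct = sprintf("%.1f", eff$per_unit_reduction_pct),
                    rr_reduction_pct = sprintf("%.2f", eff$rr_reduction_pct),
                    se_pct = eff$se_chr,
                    distribution = eff$distribution)
  utils::write.csv(eff, file.path(path, "effects.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(params$costs, file.path(path, "costs.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(params$utilities, file.path(path, "utilities.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- params$config
  yaml::write_yaml(cfg, file.path(path, "run_config.yaml"))
  invisible(path)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat(sprintf("  epidemiology: %d sex x age-band rows, %d quantities\n",
              nrow(x$epidemiology), length(epi_quantities())))
  cat(sprintf("  horizon: %d cycles; BMI change: %.2f kg/m2\n",
              x$config$horizon, x$config$bmi_change))
  cat(sprintf("  start age: men %d, women %d\n",
              x$config$start_age$men, x$config$start_age$women))
  cat(sprintf("  discounting: costs %.1f%%, QALYs %.1f%%\n",
              100 * x$config$discount$cost, 100 * x$config$discount$qaly))
  invisible(x)
}

violation <- function(field, message) {
  data.frame(field = field, message = message, stringsAsFactors = FALSE)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the parameterisation: probability
#' ranges, presence of every sex by age-band cell, ordered non-overlapping
#' age bands, non-negative costs and standard errors, utilities in [0, 1]
#' with dead pinned at 0, known distribution families matched to their
#' parameter class (costs gamma, utilities beta, risk reductions
#' lognormal), strictly positive relative risks, and a sane run
#' configuration. Violations are returned as data, not thrown.
#'
#' @param params A `parameter_set`.
#' @return Data frame with columns `field` and `message`; zero rows means
#'   the set is valid.
#' @export
validate_parameters <- function(params) {
  v <- violation(character(), character())
  epi <- params$epidemiology

  for (sx in c("men", "women")) {
    sub <- epi[epi$sex == sx, ]
    if (!nrow(sub)) {
      v <- rbind(v, violation(paste0("epidemiology.", sx), "no rows for sex"))
      next
    }
    sub <- sub[order(sub$age_lower), ]
    if (any(sub$age_lower > sub$age_upper))
      v <- rbind(v, violation(paste0("epidemiology.", sx),
                              "age band with lower > upper"))
    if (nrow(sub) > 1 && any(sub$age_lower[-1] <= sub$age_upper[-nrow(sub)]))
      v <- rbind(v, violation(paste0("epidemiology.", sx),
                              "overlapping or unordered age bands"))
  }
  bands_m <- epi[epi$sex == "men", c("age_lower", "age_upper")]
  bands_w <- epi[epi$sex == "women", c("age_lower", "age_upper")]
  if (!isTRUE(all.equal(bands_m[order(bands_m$age_lower), ],
                        bands_w[order(bands_w$age_lower), ],
                        check.attributes = FALSE)))
    v <- rbind(v, violation("epidemiology",
                            "age bands differ between sexes"))
  for (q in epi_quantities()) {
    bad <- !is.finite(epi[[q]]) | epi[[q]] < 0 | epi[[q]] > 1
    if (any(bad))
      v <- rbind(v, violation(
        paste0("epidemiology.", q),
        sprintf("probability outside [0, 100]%% in %d row(s)", sum(bad))))
  }

  eff <- params$effects
  if (any(eff$per_unit_reduction_pct < 0))
    v <- rbind(v, violation("effects.per_unit_reduction_pct",
                            "negative per-BMI-unit risk reduction"))
  if (any(eff$se_pct < 0))
    v <- rbind(v, violation("effects.se_pct", "negative SE"))
  if (any(eff$distribution != "lognormal"))
    v <- rbind(v, violation("effects.distribution",
                            "risk reductions must be lognormal"))
  derived <- eff$per_unit_reduction_pct * 0.20
  if (any(abs(derived - eff$rr_reduction_pct) > 0.005 + 1e-9))
    v <- rbind(v, violation(
      "effects.rr_reduction_pct",
      "printed total reduction does not equal per-unit reduction x 0.20"))

  cost <- params$costs
  if (any(cost$annual_cost_eur < 0))
    v <- rbind(v, violation("costs.annual_cost_eur", "negative cost"))
  if (any(cost$se_eur < 0))
    v <- rbind(v, violation("costs.se_eur", "negative SE"))
  if (any(cost$distribution != "gamma"))
    v <- rbind(v, violation("costs.distribution", "costs must be gamma"))

  util <- params$utilities
  if (any(!is.finite(util$utility) | util$utility < 0 | util$utility > 1))
    v <- rbind(v, violation("utilities.utility", "utility outside [0, 1]"))
  if (any(util$se < 0))
    v <- rbind(v, violation("utilities.se", "negative SE"))
  dead <- util$utility[util$state == "dead"]
  if (length(dead) != 1 || dead != 0)
    v <- rbind(v, violation("utilities.dead", "dead utility must be exactly 0"))
  alive_states <- setdiff(state_names(), "dead")
  miss <- setdiff(alive_states, util$state)
  if (length(miss))
    v <- rbind(v, violation("utilities.state",
                            paste("missing state(s):", paste(miss, collapse = ", "))))
  if (any(util$distribution[util$state != "dead"] != "beta"))
    v <- rbind(v, violation("utilities.distribution",
                            "utilities must be beta"))

  cfg <- params$config
  rr <- cfg$relative_risks
  if (any(unlist(rr[c("diabetes", "stroke", "chd_young", "chd_old",
                      "colon", "diabetes_to_colon")]) <= 0))
    v <- rbind(v, violation("config.relative_risks",
                            "relative risks must be strictly positive"))
  if (is.null(cfg$horizon) || cfg$horizon < 1)
    v <- rbind(v, violation("config.horizon", "horizon must be >= 1"))
  if (cfg$bmi_change < 0)
    v <- rbind(v, violation("config.bmi_change", "BMI change must be >= 0"))
  if (cfg$discount$cost < 0 || cfg$discount$qaly < 0)
    v <- rbind(v, violation("config.discount", "discount rates must be >= 0"))
  comp <- unlist(cfg$intervention_components_eur)
  if (any(comp < 0))
    v <- rbind(v, violation("config.intervention_components_eur",
                            "negative intervention cost component"))
  v
}

#' Look up an annual probability from the epidemiology table
#'
#' The published incidence and case-fatality probabilities are step
#' functions of age over 5-year bands (20-24 ... 65-69). Ages above the top
#' band are clamped to it, because a 20-year horizon started at any
#' plausible adult age outruns the table; ages below the lowest band are an
#' error, not clamped.
#'
#' @param params A `parameter_set`.
#' @param sex `"men"` or `"women"`.
#' @param age Attained age in years.
#' @param quantity One of the column names listed by the epidemiology
#'   table, e.g. `"diabetes_incidence"`.
#' @return The annual probability as a fraction.
#' @export
epi_lookup <- function(params, sex, age, quantity) {
  epi <- params$epidemiology
  stopifnot(quantity %in% epi_quantities(), sex %in% c("men", "women"))
  sub <- epi[epi$sex == sex, ]
  sub <- sub[order(sub$age_lower), ]
  if (age < sub$age_lower[1])
    stop(sprintf("age %s is below the lowest tabulated band (%d)",
                 format(age), sub$age_lower[1]))
  i <- findInterval(age, sub$age_lower)
  sub[[quantity]][i]
}

# Full epidemiology row (named fraction vector) for one sex and age.
epi_row <- function(params, sex, age) {
  epi <- params$epidemiology
  sub <- epi[epi$sex == sex, ]
  sub <- sub[order(sub$age_lower), ]
  if (age < sub$age_lower[1])
    stop(sprintf("age %s is below the lowest tabulated band (%d)",
                 format(age), sub$age_lower[1]))
  i <- findInterval(age, sub$age_lower)
  out <- as.numeric(sub[i, epi_quantities()])
  names(out) <- epi_quantities()
  out
}

#' Check the case-fatality columns against the overall-mortality column
#'
#' The model's stroke follow-up fatality is documented as twice the
#' background mortality and the diabetes fatality as 1.4 times it. This
#' diagnostic recomputes both multiples from the table and reports the
#' deviation per sex and age band (percent-point scale). In the bundled
#' tables the multiples hold to the printed precision only in the youngest
#' bands; older bands embed a larger background mortality than the printed
#' overall-mortality column, so the deviations are reported rather than
#' enforced.
#'
#' @param params A `parameter_set`.
#' @return Data frame with one row per sex and age band and the deviations
#'   `diabetes_dev` (fatality - 1.4 x mortality) and `stroke_dev`
#'   (follow-up fatality - 2 x mortality), in percent points.
#' @export
check_mortality_consistency <- function(params) {
  epi <- params$epidemiology
  data.frame(
    sex = epi$sex, age_lower = epi$age_lower, age_upper = epi$age_upper,
    diabetes_dev = 100 * (epi$diabetes_fatality - 1.4 * epi$overall_mortality),
    stroke_dev = 100 * (epi$stroke_fatality_followup - 2 * epi$overall_mortality),
    stringsAsFactors = FALSE)
}

#' Export a complete parameter set as JSON
#'
#' Archival dump of everything the model consumes, on the internal
#' (fraction) scale.
#'
#' @param params A `parameter_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_parameters_json <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# Total relative-risk reduction (fraction) for one disease/sex at a given
# BMI change.
total_reduction <- function(params, disease, sex, bmi_change) {
  eff <- params$effects
  r <- eff$per_unit_reduction[eff$disease == disease & eff$sex == sex]
  if (length(r) != 1)
    stop("no effect entry for ", disease, "/", sex)
  r * bmi_change
}

cost_of <- function(params, item) {
  x <- params$costs$annual_cost_eur[params$costs$item == item]
  if (length(x) != 1) stop("no cost entry for item ", item)
  x
}

utility_of <- function(params, state) {
  x <- params$utilities$utility[params$utilities$state == state]
  if (length(x) != 1) stop("no utility entry for state ", state)
  x
}

# State-indexed cost and utility vectors in canonical order.
state_cost_vector <- function(params) {
  c(at_risk = 0,
    diabetes = cost_of(params, "diabetes"),
    chd_1 = cost_of(params, "chd_year1"),
    chd_1plus = cost_of(params, "chd_followup"),
    stroke_1 = cost_of(params, "stroke_year1"),
    stroke_1plus = cost_of(params, "stroke_followup"),
    colon_1 = cost_of(params, "colon_year1"),
    colon_1plus = cost_of(params, "colon_followup"),
    dead = 0)
}

state_utility_vector <- function(params) {
  u <- vapply(state_names(), function(s) utility_of(params, s), numeric(1))
  names(u) <- state_names()
  u
}
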