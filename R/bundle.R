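# Country input bundle: one validated object carrying every input the model
# needs for a single country.

#' Model configuration
#'
#' @param discount_rate Annual discount rate for costs and outcomes (default 3%).
#' @param horizon_age Last modelled age; the cycle at this age is the final
#'   accounted cycle (default 89).
#' @param min_risk_age Age below which smokeless tobacco has no effect on
#'   mortality or disease prevalence (default 35).
#' @param psa_draws Number of Monte Carlo draws for the probabilistic
#'   sensitivity analysis (default 5000).
#' @param rng_seed Integer seed.
#' @param entry_bands Entering 5-year cohorts (default 15-19 through 70-74).
#' @param sexes Modelled sexes.
#' @param former_split Allocation of entering former users over the
#'   years-since-quit tunnel: `"uniform10"` spreads them evenly over tunnel
#'   years 1-10, `"long"` puts all in the 10+ state.
#' @param no_st_mortality Mortality used in the no-smokeless-tobacco
#'   counterfactual: `"never"` (never-user mortality implied by the
#'   apportionment; default) or `"population"` (the raw life-table value).
#' @return A list of class `st_config`.
#' @export
st_config <- function(discount_rate = 0.03, horizon_age = 89, min_risk_age = 35,
                      psa_draws = 5000, rng_seed = 1L,
                      entry_bands = age_bands(15, 70),
                      sexes = c("male", "female"),
                      former_split = c("uniform10", "long"),
                      no_st_mortality = c("never", "population")) {
  former_split <- match.arg(former_split)
  no_st_mortality <- match.arg(no_st_mortality)
  cfg <- list(
    discount_rate = discount_rate, horizon_age = as.integer(horizon_age),
    cycle_length = 1L, min_risk_age = as.integer(min_risk_age),
    psa_draws = as.integer(psa_draws), rng_seed = as.integer(rng_seed),
    entry_bands = entry_bands, sexes = sexes,
    former_split = former_split, no_st_mortality = no_st_mortality
  )
  class(cfg) <- "st_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$discount_rate < 0 || cfg$discount_rate >= 1) {
    rlang::abort("config: discount_rate must be in [0, 1)")
  }
  max_entry <- max(band_lower(cfg$entry_bands))
  if (cfg$horizon_age < max_entry) {
    rlang::abort("config: horizon_age must be at least the oldest entry age")
  }
  if (cfg$min_risk_age < 15 || cfg$min_risk_age > cfg$horizon_age) {
    rlang::abort("config: min_risk_age must lie within [15, horizon_age]")
  }
  if (cfg$psa_draws < 1) rlang::abort("config: psa_draws must be >= 1")
  invisible(cfg)
}

#' Assemble a country input bundle
#'
#' Collects every model input for one country into a single validated object.
#'
#' @param country Country label.
#' @param config An [st_config()].
#' @param life_table Tibble (`sex`, `age`, `q_all`): annual all-cause death
#'   probability for every integer age 15..horizon.
#' @param use_prevalence Tibble (`sex`, `age_band`, `never`, `current`,
#'   `former`): smokeless-tobacco use-state proportions summing to 1.
#' @param disease_prevalence Tibble (`disease`, `sex`, `age_band`,
#'   `prevalence`): population prevalence of the four modelled diseases.
#' @param risk_set Tibble as [default_risk_set()].
#' @param disability_weights Tibble as [default_disability_weights()].
#' @param costs One-row tibble as [default_costs()].
#' @param population Tibble (`sex`, `age_band`, `population`).
#' @param distributions Tibble as [default_distributions()].
#' @param schedule Optional calibrated [st_schedule] (else produced later by
#'   [calibrate_transitions()]).
#' @return A list of class `st_bundle`.
#' @export
st_bundle <- function(country, config, life_table, use_prevalence,
                      disease_prevalence, risk_set = default_risk_set(),
                      disability_weights = default_disability_weights(),
                      costs = default_costs(country),
                      population = NULL,
                      distributions = default_distributions(country),
                      schedule = NULL) {
  # canonical row order and bare (unnamed) columns, so that write/read is the
  # identity regardless of how the tables were assembled
  canon <- function(d, ...) {
    d <- dplyr::mutate(tibble::as_tibble(d),
                       dplyr::across(dplyr::everything(), unname))
    dplyr::arrange(d, ...)
  }
  bundle <- list(
    country = country, config = config,
    life_table = canon(life_table, .data$sex, .data$age),
    use_prevalence = canon(use_prevalence, .data$sex,
                           band_lower(.data$age_band)),
    disease_prevalence = canon(disease_prevalence, .data$disease, .data$sex,
                               band_lower(.data$age_band)),
    risk_set = tibble::as_tibble(risk_set),
    disability_weights = canon(disability_weights, .data$disease, .data$sex,
                               .data$age_group),
    costs = tibble::as_tibble(costs),
    population = if (!is.null(population)) {
      canon(population, .data$sex, band_lower(.data$age_band))
    },
    distributions = tibble::as_tibble(distributions),
    schedule = schedule
  )
  class(bundle) <- "st_bundle"
  validate_bundle(bundle)
}

#' Validate a country input bundle
#'
#' Checks every structural invariant: complete age grids, use-state proportions
#' summing to 1, probabilities within range, relative risks positive and
#' non-increasing with time since quitting (returning to 1 at 10+ years),
#' disability weights in (0,1), non-negative costs with prevalent-stroke cost
#' not exceeding incident, and distribution parameters consistent with their
#' point estimates. Any breach is a hard error naming the offending table and
#' row.
#'
#' @param bundle An `st_bundle`.
#' @return The bundle, invisibly usable, on success.
#' @export
validate_bundle <- function(bundle) {
  cfg <- bundle$config
  validate_config(cfg)
  fail <- function(...) rlang::abort(paste0("bundle validation: ", ...))

  # life table: full grid, probabilities in range
  lt <- bundle$life_table
  need <- tidyr::crossing(sex = cfg$sexes, age = 15:cfg$horizon_age)
  missing <- dplyr::anti_join(need, lt, by = c("sex", "age"))
  if (nrow(missing) > 0) {
    fail("life_table missing (sex, age) rows, e.g. ",
         missing$sex[1], " age ", missing$age[1])
  }
  if (any(lt$q_all < 0 | lt$q_all > 1)) fail("life_table q_all outside [0, 1]")

  # use prevalence: every entry band, triples sum to 1
  up <- bundle$use_prevalence
  need_b <- tidyr::crossing(sex = cfg$sexes, age_band = cfg$entry_bands)
  missing <- dplyr::anti_join(need_b, up, by = c("sex", "age_band"))
  if (nrow(missing) > 0) {
    fail("use_prevalence missing band ", missing$age_band[1],
         " for ", missing$sex[1])
  }
  comp <- as.matrix(up[, c("never", "current", "former")])
  if (any(comp < 0 | comp > 1)) fail("use_prevalence components outside [0, 1]")
  s <- rowSums(comp)
  bad <- which(abs(s - 1) > 1e-9)
  if (length(bad) > 0) {
    fail("use_prevalence components do not sum to 1 in band ",
         up$age_band[bad[1]], " (", up$sex[bad[1]], "): sum = ",
         format(s[bad[1]], digits = 12))
  }

  # disease prevalence: all four diseases on the full band grid, in [0, 1)
  dp <- bundle$disease_prevalence
  need_d <- tidyr::crossing(
    disease = st_diseases(), sex = cfg$sexes,
    age_band = age_bands(15, (cfg$horizon_age %/% 5) * 5)
  )
  missing <- dplyr::anti_join(need_d, dp, by = c("disease", "sex", "age_band"))
  if (nrow(missing) > 0) {
    fail("disease_prevalence missing ", missing$disease[1], " ",
         missing$sex[1], " band ", missing$age_band[1])
  }
  if (any(dp$prevalence < 0 | dp$prevalence >= 1)) {
    fail("disease_prevalence values must lie in [0, 1)")
  }

  # risk set: every outcome, positive, non-increasing, 10+ exactly 1
  rs <- bundle$risk_set
  if (!setequal(rs$outcome, st_outcomes())) {
    fail("risk_set must contain exactly the outcomes: ",
         paste(st_outcomes(), collapse = ", "))
  }
  m <- as.matrix(rs[, c("current", "former_0_4", "former_5_10", "former_10plus")])
  if (any(m <= 0)) fail("risk_set multipliers must be positive")
  if (any(rs$former_10plus != 1)) {
    fail("risk_set former_10plus must equal 1 exactly (risk returns to ",
         "never-user level 10 years after quitting)")
  }
  nonmono <- which(m[, 1] < m[, 2] | m[, 2] < m[, 3] | m[, 3] < m[, 4])
  if (length(nonmono) > 0) {
    fail("risk_set multipliers must be non-increasing with time since ",
         "quitting (outcome ", rs$outcome[nonmono[1]], ")")
  }

  # disability weights in (0, 1) on the full (disease, sex, group) grid
  dw <- bundle$disability_weights
  need_w <- tidyr::crossing(disease = st_diseases(), sex = cfg$sexes,
                            age_group = c("15-49", "50-69", "70+"))
  missing <- dplyr::anti_join(need_w, dw, by = c("disease", "sex", "age_group"))
  if (nrow(missing) > 0) {
    fail("disability_weights missing ", missing$disease[1], " ",
         missing$sex[1], " ", missing$age_group[1])
  }
  if (any(dw$weight <= 0 | dw$weight >= 1)) {
    fail("disability_weights must lie strictly in (0, 1)")
  }

  # costs
  ct <- bundle$costs
  if (any(c(ct$annual_cancer_cost, ct$incident_stroke_cost,
            ct$prevalent_stroke_cost) < 0)) {
    fail("costs must be non-negative")
  }
  if (ct$prevalent_stroke_cost > ct$incident_stroke_cost) {
    fail("prevalent_stroke_cost must not exceed incident_stroke_cost")
  }
  if (ct$incident_stroke_fraction < 0 || ct$incident_stroke_fraction > 1) {
    fail("incident_stroke_fraction must lie in [0, 1]")
  }

  # population
  if (!is.null(bundle$population)) {
    if (any(bundle$population$population < 0)) fail("population counts must be >= 0")
  }

  # distributions: parameters in domain, consistent with point estimates
  di <- bundle$distributions
  for (k in seq_len(nrow(di))) {
    row <- di[k, ]
    ok <- switch(row$kind,
      lognormal = row$par2 > 0 &&
        abs(exp(row$par1) - row$point) <= 0.02 * row$point,
      beta = row$par1 > 0 && row$par2 > 0 &&
        abs(row$par1 / (row$par1 + row$par2) - row$point) <= 1e-6,
      gamma = row$par1 > 0 && row$par2 > 0,
      fixed = TRUE,
      FALSE
    )
    if (!isTRUE(ok)) {
      fail("distribution '", row$name, "' (", row$kind,
           ") has parameters inconsistent with its point estimate or domain")
    }
  }

  bundle
}

#' @export
print.st_bundle <- function(x, ...) {
  cat("<st_bundle> country:", x$country, "\n")
  cat("  sexes:", paste(x$config$sexes, collapse = ", "),
      " entry bands:", x$config$entry_bands[1], "..",
      x$config$entry_bands[length(x$config$entry_bands)], "\n")
  cat("  horizon age:", x$config$horizon_age,
      " discount rate:", x$config$discount_rate, "\n")
  cat("  schedule:", if (is.null(x$schedule)) "not yet calibrated" else "calibrated", "\n")
  invisible(x)
}
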