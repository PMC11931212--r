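# Packaged default parameter tables: pooled meta-analytic relative risks,
# GBD-derived disability weights, country unit costs and their uncertainty
# distributions. These ship with the package so a bundle can be assembled
# from demography alone.

#' Default relative-risk set
#'
#' Relative risks of all-cause mortality and of the four modelled diseases for
#' smokeless tobacco users versus never users, by exposure class. Risk decays
#' with time since quitting and returns to the never-user level 10 years after
#' quitting, so the `former_10plus` column is exactly 1.
#'
#' @return A tibble with one row per outcome and columns `outcome`, `current`,
#'   `former_0_4`, `former_5_10`, `former_10plus`.
#' @export
default_risk_set <- function() {
  tibble::tribble(
    ~outcome,            ~current, ~former_0_4, ~former_5_10, ~former_10plus,
    "mortality",             1.25,        1.09,         1.02,              1,
    "esophageal_cancer",     3.17,        1.77,         1.21,              1,
    "oral_cancer",           5.55,        2.61,         1.45,              1,
    "pharyngeal_cancer",     2.69,        1.56,         1.16,              1,
    "stroke",                1.37,        1.13,         1.04,              1
  )
}

#' Default disability weights
#'
#' Average disability weight per prevalent case, by disease and coarse age
#' group (15-49, 50-69, 70+), derived from stage/severity-weighted GBD 2016
#' weights. The same weights apply to both sexes.
#'
#' @return A tibble with columns `disease`, `sex`, `age_group`, `weight`.
#' @export
default_disability_weights <- function() {
  base <- tibble::tribble(
    ~disease,            ~age_group, ~weight,
    "oral_cancer",       "15-49",      0.164,
    "oral_cancer",       "50-69",      0.172,
    "oral_cancer",       "70+",        0.196,
    "esophageal_cancer", "15-49",      0.143,
    "esophageal_cancer", "50-69",      0.165,
    "esophageal_cancer", "70+",        0.191,
    "pharyngeal_cancer", "15-49",      0.207,
    "pharyngeal_cancer", "50-69",      0.236,
    "pharyngeal_cancer", "70+",        0.370,
    "stroke",            "15-49",      0.210,
    "stroke",            "50-69",      0.236,
    "stroke",            "70+",        0.375
  )
  tidyr::crossing(sex = c("male", "female"), base) |>
    dplyr::select("disease", "sex", "age_group", "weight")
}

#' Default disease unit costs (US dollars)
#'
#' Annual treatment cost per prevalent cancer case, first-year (incident) and
#' subsequent-year (prevalent) stroke costs, and the proportion of prevalent
#' strokes that are within their first year. Prevalent-stroke cost is 10% of
#' the incident cost. India and Pakistan share one cost set.
#'
#' @param country `"india"`, `"pakistan"` or `"bangladesh"` (case-insensitive).
#' @return A one-row tibble with columns `country`, `annual_cancer_cost`,
#'   `incident_stroke_cost`, `prevalent_stroke_cost`, `incident_stroke_fraction`.
#' @export
default_costs <- function(country = "india") {
  country <- tolower(country)
  if (!country %in% c("india", "pakistan", "bangladesh")) {
    rlang::abort(paste0("unknown country for default costs: '", country, "'"))
  }
  if (country %in% c("india", "pakistan")) {
    tibble::tibble(
      country = country,
      annual_cancer_cost = 2164,
      incident_stroke_cost = 821,
      prevalent_stroke_cost = 82,
      incident_stroke_fraction = 0.10
    )
  } else {
    tibble::tibble(
      country = country,
      annual_cancer_cost = 791,
      incident_stroke_cost = 601,
      prevalent_stroke_cost = 60,
      incident_stroke_fraction = 0.10
    )
  }
}

#' Default parameter-uncertainty distributions
#'
#' One row per uncertain parameter used by the probabilistic sensitivity
#' analysis: lognormal for relative risks (parameterised by the log of the
#' mean and its standard error), beta for disability weights and the
#' incident-stroke fraction, gamma for unit costs.
#'
#' Printed gamma parameters for costs are not consistent with the USD point
#' estimates (they appear to be on another currency scale), so by default
#' costs are sampled as Gamma(shape = 100, scale = point/100), i.e. a 10%
#' coefficient of variation matching shape 100; `gamma_mode = "table1"`
#' retains the verbatim printed (shape = 100, scale) pairs instead.
#'
#' @param country Country whose costs to parameterise.
#' @param gamma_mode `"cv10"` (default) or `"table1"`.
#' @return A tibble with columns `name`, `target`, `outcome`, `stratum`,
#'   `kind`, `par1`, `par2`, `point`. For lognormal, `par1`/`par2` are the log
#'   mean and its SE; for beta, alpha and beta; for gamma, shape and scale.
#' @export
default_distributions <- function(country = "india", gamma_mode = c("cv10", "table1")) {
  gamma_mode <- match.arg(gamma_mode)
  rr <- tibble::tribble(
    ~outcome,            ~stratum,      ~par1, ~par2, ~point,
    "mortality",         "current",      0.22,  0.07,   1.25,
    "mortality",         "former_0_4",   0.08,  0.10,   1.09,
    "mortality",         "former_5_10",  0.02,  0.10,   1.02,
    "esophageal_cancer", "current",      1.15,  0.07,   3.17,
    "esophageal_cancer", "former_0_4",   0.56,  0.10,   1.77,
    "esophageal_cancer", "former_5_10",  0.18,  0.10,   1.21,
    "oral_cancer",       "current",      1.71,  0.05,   5.55,
    "oral_cancer",       "former_0_4",   0.95,  0.10,   2.61,
    "oral_cancer",       "former_5_10",  0.36,  0.10,   1.45,
    "pharyngeal_cancer", "current",      0.99,  0.08,   2.69,
    "pharyngeal_cancer", "former_0_4",   0.44,  0.10,   1.56,
    "pharyngeal_cancer", "former_5_10",  0.14,  0.10,   1.16,
    "stroke",            "current",      0.31,  0.12,   1.37,
    "stroke",            "former_0_4",   0.12,  0.10,   1.13,
    "stroke",            "former_5_10",  0.03,  0.10,   1.04
  ) |>
    dplyr::mutate(
      name = paste("rr", .data$outcome, .data$stratum, sep = "_"),
      target = "risk", kind = "lognormal"
    )

  dw <- default_disability_weights() |>
    dplyr::filter(.data$sex == "male") |>
    dplyr::transmute(
      outcome = .data$disease,
      stratum = .data$age_group,
      par1 = .data$weight * 50,
      par2 = 50 - .data$weight * 50,
      point = .data$weight,
      name = paste("dw", .data$outcome, gsub("[-+]", "_", .data$stratum), sep = "_"),
      target = "weight", kind = "beta"
    )

  costs <- default_costs(country)
  table1_scale <- if (costs$country %in% c("india", "pakistan")) {
    c(cancer = 1523.68, incident_stroke = 578.04, prevalent_stroke = 57.80)
  } else {
    c(cancer = 667.90, incident_stroke = 507.77, prevalent_stroke = 50.78)
  }
  points <- c(
    cancer = costs$annual_cancer_cost,
    incident_stroke = costs$incident_stroke_cost,
    prevalent_stroke = costs$prevalent_stroke_cost
  )
  scale <- if (gamma_mode == "cv10") points / 100 else table1_scale
  cost_rows <- tibble::tibble(
    outcome = names(points),
    stratum = NA_character_,
    par1 = 100,
    par2 = unname(scale),
    point = unname(points),
    name = paste0("cost_", names(points)),
    target = "cost", kind = "gamma"
  )

  frac <- tibble::tibble(
    outcome = "stroke", stratum = "incident_fraction",
    par1 = 5, par2 = 45, point = 0.10,
    name = "incident_stroke_fraction", target = "fraction", kind = "beta"
  )

  dplyr::bind_rows(rr, dw, cost_rows, frac) |>
    dplyr::select("name", "target", "outcome", "stratum", "kind", "par1", "par2", "point")
}

#' Default annual relapse schedule
#'
#' Annual probability of relapsing to current use by year since quitting.
#' Relapse declines geometrically over tunnel years 1-10 with no long-term
#' relapse after 10 years.
#'
#' @param first_year Relapse probability in the first year since quitting.
#' @param decay Multiplicative decline per additional year since quitting.
#' @param tail Relapse probability in the 10+ state.
#' @return A list with `prob` (length-10 numeric, tunnel years 1-10) and
#'   `tail` (scalar).
#' @export
default_relapse <- function(first_year = 0.10, decay = 0.6, tail = 0) {
  stopifnot(first_year >= 0, first_year <= 1, decay >= 0, decay <= 1,
            tail >= 0, tail <= 1)
  list(prob = first_year * decay^(0:9), tail = tail)
}
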