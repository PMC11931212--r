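# Relative-risk apportionment: convert a population-level annual probability
# or prevalence into exposure-class-specific values such that the
# share-weighted mean reproduces the population value exactly, and compute
# population attributable fractions.

#' Effective risk multipliers at a given age
#'
#' Returns the relative-risk multipliers for the five exposure classes for one
#' outcome. Below `min_risk_age` smokeless tobacco is assumed not to affect
#' mortality or disease prevalence, so all multipliers are 1.
#'
#' @param risk_set Tibble as [default_risk_set()].
#' @param outcome One of [st_outcomes()].
#' @param age Integer age in years.
#' @param min_risk_age Age below which exposure carries no excess risk.
#' @return Named numeric vector over [st_classes()].
#' @export
effective_multipliers <- function(risk_set, outcome, age, min_risk_age = 35) {
  row <- risk_set[risk_set$outcome == outcome, ]
  if (nrow(row) != 1) {
    rlang::abort(paste0("unknown outcome '", outcome, "' in risk set"))
  }
  if (age < min_risk_age) {
    out <- rep(1, 5)
  } else {
    out <- c(1, row$current, row$former_0_4, row$former_5_10, row$former_10plus)
  }
  stats::setNames(out, st_classes())
}

#' Apportion a population rate across exposure classes
#'
#' Given a population-level annual probability or prevalence, the exposure
#' shares of the population, and relative-risk multipliers, solves for the
#' never-user rate `r_never = rate / sum(shares * mult)` and returns
#' `mult * r_never` per class. The share-weighted mean of the result equals the
#' population rate (conservation). Class rates are capped at 1 with a warning
#' if the cap binds.
#'
#' @param pop_rate Population rate in `[0, 1)`.
#' @param shares Exposure-class shares over [st_classes()], summing to 1.
#' @param multipliers Relative risks per class (never = 1).
#' @return Named numeric vector of class-specific rates.
#' @export
status_specific_rate <- function(pop_rate, shares, multipliers) {
  if (pop_rate < 0 || pop_rate >= 1) {
    rlang::abort("pop_rate must lie in [0, 1)")
  }
  if (abs(sum(shares) - 1) > 1e-9) {
    rlang::abort("exposure shares must sum to 1")
  }
  r_never <- pop_rate / sum(shares * multipliers)
  out <- multipliers * r_never
  if (any(out > 1)) {
    rlang::warn("status-specific rate capped at 1; conservation no longer exact")
    out <- pmin(out, 1)
  }
  stats::setNames(out, st_classes())
}

#' Population attributable fraction
#'
#' Proportion of an outcome attributable to exposure, from exposure shares and
#' relative risks: `sum(shares * (mult - 1)) / (1 + sum(shares * (mult - 1)))`.
#' Equivalent to `1 - r_never / pop_rate` under [status_specific_rate()].
#'
#' @inheritParams status_specific_rate
#' @return A proportion in `[0, 1)` when all multipliers are at least 1.
#' @export
attributable_fraction <- function(shares, multipliers) {
  if (abs(sum(shares) - 1) > 1e-9) {
    rlang::abort("exposure shares must sum to 1")
  }
  excess <- sum(shares * (multipliers - 1))
  excess / (1 + excess)
}
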