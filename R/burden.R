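# Burden accounting: turn state-occupancy traces into discounted lifetime
# costs, life years, years lived with disability (YLD) and DALYs; compute the
# smokeless-tobacco-attributable burden as the difference between the
# status-quo and no-use scenarios; scale to cohort populations.

#' Discounted total of a per-cycle series
#'
#' `sum(series / (1 + rate)^t)` with `t = 0` at cohort entry.
#'
#' @param series Numeric per-cycle values, first element at entry.
#' @param rate Annual discount rate in `[0, 1)`.
#' @return Scalar discounted total.
#' @export
discounted_total <- function(series, rate) {
  if (rate < 0 || rate >= 1) rlang::abort("discount rate must lie in [0, 1)")
  sum(series / (1 + rate)^(seq_along(series) - 1))
}

# Unit annual cost per prevalent case, by disease.
unit_costs <- function(costs) {
  stroke <- costs$incident_stroke_fraction * costs$incident_stroke_cost +
    (1 - costs$incident_stroke_fraction) * costs$prevalent_stroke_cost
  stats::setNames(
    c(rep(costs$annual_cancer_cost, 3), stroke),
    c("oral_cancer", "pharyngeal_cancer", "esophageal_cancer", "stroke")
  )
}

#' Exposure-class disease prevalence for one cycle
#'
#' Apportions the population prevalence of each disease across exposure
#' classes at a given age using the alive exposure shares of the cycle. The
#' share-weighted mean of the class prevalences reproduces the population
#' prevalence (conservation).
#'
#' @param bundle An [st_bundle()].
#' @param sex,age Cohort sex and current age.
#' @param shares Alive exposure-class shares over [st_classes()].
#' @return Tibble (`disease`, `class`, `prevalence`, `population_prevalence`).
#' @export
cycle_disease_burden <- function(bundle, sex, age, shares) {
  dp <- bundle$disease_prevalence
  band <- age_to_band(age)
  purrr::map_dfr(st_diseases(), function(d) {
    p <- dp$prevalence[dp$disease == d & dp$sex == sex & dp$age_band == band]
    if (length(p) != 1) {
      rlang::abort(paste0("missing disease prevalence: ", d, " ", sex,
                          " band ", band))
    }
    mult <- effective_multipliers(bundle$risk_set, d, age,
                                  bundle$config$min_risk_age)
    r <- status_specific_rate(p, shares, mult)
    tibble::tibble(disease = d, class = st_classes(), prevalence = unname(r),
                   population_prevalence = p)
  })
}

# Occupancy collapsed onto the five alive exposure classes.
class_occupancy <- function(occ_row) {
  idx <- state_class_index()[1:13]
  stats::setNames(
    vapply(1:5, function(k) sum(occ_row[1:13][idx == k]), numeric(1)),
    st_classes()
  )
}

#' Cost accrued per cohort member in one cycle
#'
#' Cancers cost the annual per-prevalent-case amount; stroke costs a blend of
#' first-year (incident) and subsequent-year (prevalent) costs weighted by the
#' incident fraction. Costs accrue to the alive occupancy at cycle start,
#' weighted by the exposure-class-specific disease prevalence.
#'
#' @param class_prev Tibble from [cycle_disease_burden()].
#' @param occ_row Occupancy vector over [st_states()] at cycle start.
#' @param costs One-row cost tibble from the bundle.
#' @return Expected cost per entering cohort member this cycle.
#' @export
cycle_cost <- function(class_prev, occ_row, costs) {
  uc <- unit_costs(costs)
  occ_c <- class_occupancy(occ_row)
  class_prev |>
    dplyr::mutate(
      occ = occ_c[.data$class],
      contribution = .data$occ * .data$prevalence * uc[.data$disease]
    ) |>
    dplyr::pull(.data$contribution) |>
    sum()
}

#' Years lived with disability per cohort member in one cycle
#'
#' Sum over diseases of occupancy-weighted prevalence times the disability
#' weight for that disease, sex and age group; disutility is additive across
#' diseases.
#'
#' @inheritParams cycle_cost
#' @param weights Disability-weight tibble from the bundle.
#' @param sex,age Cohort sex and current age.
#' @return Expected YLD per entering cohort member this cycle.
#' @export
cycle_yld <- function(class_prev, occ_row, weights, sex, age) {
  wb <- age_to_weight_band(age)
  w <- weights[weights$sex == sex & weights$age_group == wb, ]
  wmap <- stats::setNames(w$weight, w$disease)
  occ_c <- class_occupancy(occ_row)
  class_prev |>
    dplyr::mutate(
      occ = occ_c[.data$class],
      contribution = .data$occ * .data$prevalence * wmap[.data$disease]
    ) |>
    dplyr::pull(.data$contribution) |>
    sum()
}

# Per-cycle series for both scenarios from one status-quo engine run.
# Returns everything burden_for_cohort and the attribution need.
burden_core <- function(bundle, eng) {
  cfg <- bundle$config
  sex <- eng$sex
  n <- length(eng$ages)
  dp <- bundle$disease_prevalence[bundle$disease_prevalence$sex == sex, ]
  dw <- bundle$disability_weights[bundle$disability_weights$sex == sex, ]
  uc <- unit_costs(bundle$costs)
  diseases <- st_diseases()

  q_never <- if (cfg$no_st_mortality == "never") eng$q_class[, "never"] else eng$q_all
  alive_sq <- 1 - eng$occ[, 14]
  alive_ns <- numeric(n)
  alive_ns[1] <- 1
  for (t in seq_len(n - 1)) alive_ns[t + 1] <- alive_ns[t] * (1 - q_never[t])

  # class prevalence per cycle x disease (5 cols per disease), plus the
  # never-user prevalence used by the counterfactual
  prev_class <- array(0, c(n, length(diseases), 5),
                      dimnames = list(NULL, diseases, st_classes()))
  yld_w <- matrix(0, n, length(diseases), dimnames = list(NULL, diseases))
  for (t in seq_len(n)) {
    a <- eng$ages[t]
    band <- age_to_band(a)
    wb <- age_to_weight_band(a)
    for (d in diseases) {
      p <- dp$prevalence[dp$disease == d & dp$age_band == band]
      mult <- effective_multipliers(bundle$risk_set, d, a, cfg$min_risk_age)
      prev_class[t, d, ] <- status_specific_rate(p, eng$shares[t, ], mult)
      yld_w[t, d] <- dw$weight[dw$disease == d & dw$age_group == wb]
    }
  }

  # status-quo per-cycle cost and YLD per cohort member: occupancy-weighted
  # class prevalence; by conservation this equals alive * population prevalence
  idx <- state_class_index()[1:13]
  occ_class <- t(apply(eng$occ[, 1:13, drop = FALSE], 1, function(r) {
    vapply(1:5, function(k) sum(r[idx == k]), numeric(1))
  }))
  cost_sq_d <- matrix(0, n, length(diseases), dimnames = list(NULL, diseases))
  yld_sq_d <- cost_ns_d <- yld_ns_d <- cost_sq_d
  for (d in diseases) {
    wprev <- rowSums(occ_class * prev_class[, d, ])
    cost_sq_d[, d] <- wprev * uc[[d]]
    yld_sq_d[, d] <- wprev * yld_w[, d]
    p_never <- prev_class[, d, "never"]
    cost_ns_d[, d] <- alive_ns * p_never * uc[[d]]
    yld_ns_d[, d] <- alive_ns * p_never * yld_w[, d]
  }

  list(n = n, ages = eng$ages, alive_sq = alive_sq, alive_ns = alive_ns,
       q_never = q_never, prev_class = prev_class, yld_w = yld_w, uc = uc,
       cost_sq_d = cost_sq_d, yld_sq_d = yld_sq_d,
       cost_ns_d = cost_ns_d, yld_ns_d = yld_ns_d)
}

#' Lifetime attributable burden for one cohort
#'
#' Runs the status-quo and no-use scenarios for one entering age-sex cohort
#' and accumulates discounted life years (alive fraction per cycle), YLD and
#' treatment costs. Attributable burden is the scenario difference: life years
#' gained (`no_st - status_quo`), YLD averted and costs saved
#' (`status_quo - no_st`), with DALYs averted their sum. All values are per
#' entering cohort member; population scaling happens in
#' [aggregate_country()].
#'
#' @inheritParams run_cohort
#' @return A list of class `st_burden` with elements `sex`, `entry_band`,
#'   `scenarios` (tibble of discounted totals per scenario), `by_disease`
#'   (discounted cost and YLD per disease and scenario), and the per-individual
#'   differences `d_ly`, `d_yld`, `d_cost`, `dalys_averted`.
#' @export
burden_for_cohort <- function(bundle, sex, entry_band,
                              schedule = bundle$schedule) {
  if (is.null(schedule)) {
    rlang::abort("no schedule supplied and bundle has none; run calibrate_transitions()")
  }
  eng <- engine_run(bundle, sex, entry_band, schedule)
  core <- burden_core(bundle, eng)
  r <- bundle$config$discount_rate

  disc <- function(x) discounted_total(x, r)
  ly_sq <- disc(core$alive_sq); ly_ns <- disc(core$alive_ns)
  yld_sq <- disc(rowSums(core$yld_sq_d)); yld_ns <- disc(rowSums(core$yld_ns_d))
  cost_sq <- disc(rowSums(core$cost_sq_d)); cost_ns <- disc(rowSums(core$cost_ns_d))

  by_disease <- purrr::map_dfr(st_diseases(), function(d) {
    tibble::tibble(
      disease = d,
      cost_status_quo = disc(core$cost_sq_d[, d]),
      cost_no_st = disc(core$cost_ns_d[, d]),
      yld_status_quo = disc(core$yld_sq_d[, d]),
      yld_no_st = disc(core$yld_ns_d[, d])
    ) |>
      dplyr::mutate(d_cost = .data$cost_status_quo - .data$cost_no_st,
                    d_yld = .data$yld_status_quo - .data$yld_no_st)
  })

  out <- list(
    sex = sex, entry_band = entry_band,
    discount_rate = r,
    scenarios = tibble::tibble(
      scenario = c("status_quo", "no_st"),
      life_years = c(ly_sq, ly_ns),
      yld = c(yld_sq, yld_ns),
      cost = c(cost_sq, cost_ns)
    ),
    by_disease = by_disease,
    d_ly = ly_ns - ly_sq,
    d_yld = yld_sq - yld_ns,
    d_cost = cost_sq - cost_ns,
    dalys_averted = (ly_ns - ly_sq) + (yld_sq - yld_ns)
  )
  class(out) <- "st_burden"
  out
}

#' @export
print.st_burden <- function(x, ...) {
  cat("<st_burden>", x$sex, "cohort entering at", x$entry_band, "\n")
  cat(sprintf("  per individual: %+.4f life years, %+.4f DALYs averted, %+.2f cost saved\n",
              x$d_ly, x$dalys_averted, x$d_cost))
  invisible(x)
}

#' Tidy a cohort burden result
#'
#' @param x An `st_burden`.
#' @param ... Unused.
#' @return A one-row tibble of the per-individual attributable quantities.
#' @export
tidy.st_burden <- function(x, ...) {
  tibble::tibble(
    sex = x$sex, entry_band = x$entry_band,
    life_years_gained = x$d_ly, yld_averted = x$d_yld,
    dalys_averted = x$dalys_averted, cost_saved = x$d_cost
  )
}

#' Attribute cohort costs to the state at entry
#'
#' Splits the cohort's attributable cost across those who enter the model as
#' never, current and former users. Each entry-state sub-cohort is propagated
#' through the full cohort's transition matrices and compared against its own
#' never-forever baseline, so the entry-share-weighted attributable costs sum
#' exactly to the full cohort's attributable cost.
#'
#' @inheritParams run_cohort
#' @return Tibble (`entry_state`, `weight`, `attributable_cost`, `share`).
#'   When the weighted total is zero the shares are `NA` (undefined), never
#'   `NaN`.
#' @export
attribute_by_entry_state <- function(bundle, sex, entry_band,
                                     schedule = bundle$schedule) {
  if (is.null(schedule)) {
    rlang::abort("no schedule supplied and bundle has none; run calibrate_transitions()")
  }
  eng <- engine_run(bundle, sex, entry_band, schedule)
  core <- burden_core(bundle, eng)
  r <- bundle$config$discount_rate
  n <- core$n
  idx <- state_class_index()[1:13]

  # never-forever baseline cost series per unit of entering mass
  base_cost <- rowSums(core$cost_ns_d)
  base_total <- discounted_total(base_cost, r)

  sub <- run_subcohorts_by_initial_state(bundle, sex, entry_band, schedule)
  rows <- purrr::imap_dfr(sub$traces, function(tr, nm) {
    occ <- as.matrix(tr[, st_states()])
    occ_class <- t(apply(occ[, 1:13, drop = FALSE], 1, function(rr) {
      vapply(1:5, function(k) sum(rr[idx == k]), numeric(1))
    }))
    cost_series <- numeric(n)
    for (d in st_diseases()) {
      cost_series <- cost_series +
        rowSums(occ_class * core$prev_class[, d, ]) * core$uc[[d]]
    }
    tibble::tibble(
      entry_state = nm,
      weight = sub$weights[[nm]],
      attributable_cost = discounted_total(cost_series, r) - base_total
    )
  })
  total <- sum(rows$weight * rows$attributable_cost)
  rows$share <- if (abs(total) > 1e-9) {
    rows$weight * rows$attributable_cost / total
  } else {
    NA_real_
  }
  rows
}

#' Country-level population-scaled burden
#'
#' Computes the per-individual attributable burden for every (sex, entry band)
#' cohort, scales by the cohort population, and returns the stratified table
#' with country totals attached.
#'
#' @param bundle An [st_bundle()] with a `population` table.
#' @param schedule An [st_schedule()]; defaults to the bundle's.
#' @return A tibble of class `st_country_burden`, one row per (sex, entry
#'   band), with per-individual and total columns; country totals are in
#'   `attr(, "totals")`.
#' @export
aggregate_country <- function(bundle, schedule = bundle$schedule) {
  if (is.null(bundle$population)) {
    rlang::abort("bundle has no population table; aggregate_country needs one")
  }
  cfg <- bundle$config
  rows <- purrr::map_dfr(cfg$sexes, function(sx) {
    purrr::map_dfr(cfg$entry_bands, function(b) {
      res <- burden_for_cohort(bundle, sx, b, schedule)
      pop <- bundle$population$population[
        bundle$population$sex == sx & bundle$population$age_band == b]
      if (length(pop) != 1) {
        rlang::abort(paste0("population missing for ", sx, " band ", b))
      }
      tidy(res) |>
        dplyr::mutate(
          population = pop,
          total_cost_saved = .data$cost_saved * pop,
          total_dalys_averted = .data$dalys_averted * pop,
          total_life_years_gained = .data$life_years_gained * pop
        )
    })
  })
  totals <- rows |>
    dplyr::summarise(
      total_cost_saved = sum(.data$total_cost_saved),
      total_dalys_averted = sum(.data$total_dalys_averted),
      total_life_years_gained = sum(.data$total_life_years_gained)
    )
  attr(rows, "totals") <- totals
  attr(rows, "country") <- bundle$country
  class(rows) <- c("st_country_burden", class(rows))
  rows
}
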