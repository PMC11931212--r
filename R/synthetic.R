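# Synthetic country bundle generator: statistically plausible demography,
# use prevalence and disease prevalence so the whole pipeline can run and be
# tested without any external data download.

#' Generate a synthetic country input bundle
#'
#' Produces a fully valid [st_bundle()] emulating the shape of the real
#' inputs: Gompertz-increasing all-cause mortality; hump-shaped current-use
#' prevalence by age (low in adolescence, peaking in middle age) with a
#' never-user share that declines monotonically with age and sex-specific
#' levels (male use about twice female); disease prevalence rising with age;
#' packaged default relative risks, disability weights, costs and
#' distributions; and a population that declines with age. Deterministic given
#' the seed.
#'
#' @param seed Integer seed.
#' @param country Country label controlling the packaged cost set.
#' @param current_use_scale Multiplier on current-use prevalence; `0` yields a
#'   bundle with no smokeless tobacco use at all (every downstream
#'   attributable quantity is then 0).
#' @param mortality_scale Multiplier on annual death probabilities.
#' @param config An [st_config()]; the default uses `seed` as the RNG seed.
#' @param jitter Relative scale of the multiplicative noise applied to
#'   prevalence curves (default 2%); `0` gives perfectly smooth curves.
#' @return A validated [st_bundle()].
#' @export
synthetic_bundle <- function(seed = 1L, country = "india",
                             current_use_scale = 1, mortality_scale = 1,
                             config = st_config(rng_seed = as.integer(seed)),
                             jitter = 0.02) {
  if (current_use_scale < 0 || current_use_scale > 1.5) {
    rlang::abort("current_use_scale must lie in [0, 1.5]")
  }
  if (mortality_scale <= 0 || mortality_scale > 3) {
    rlang::abort("mortality_scale must lie in (0, 3]")
  }
  if (jitter < 0 || jitter > 0.2) rlang::abort("jitter must lie in [0, 0.2]")

  withr::with_seed(as.integer(seed), {
    horizon <- config$horizon_age
    ages <- 15:horizon

    # Gompertz-like mortality, male excess
    life_table <- tidyr::crossing(sex = config$sexes, age = ages) |>
      dplyr::mutate(
        base = 8e-5 * exp(0.085 * .data$age),
        q_all = pmin(.data$base * ifelse(.data$sex == "male", 1.2, 1.0) *
                       mortality_scale, 0.99)
      ) |>
      dplyr::select("sex", "age", "q_all")

    # use prevalence: ever-use rises with age (never share monotone down),
    # the current fraction of ever-users declines with age (quitting), giving
    # a hump-shaped current-use curve
    bands <- config$entry_bands
    lo <- band_lower(bands)
    noise <- function(n) exp(stats::rnorm(n, 0, jitter))
    use_prevalence <- tidyr::crossing(sex = config$sexes, lb = lo) |>
      dplyr::mutate(
        level = ifelse(.data$sex == "male", 0.55, 0.28),
        ever = pmin((0.04 + .data$level * (1 - exp(-0.045 * (.data$lb - 15)))) *
                      noise(dplyr::n()) * current_use_scale, 0.95),
        frac_current = pmax(pmin(0.95 - 0.0065 * (.data$lb - 15), 1), 0.05),
        current = .data$ever * .data$frac_current,
        former = .data$ever - .data$current,
        never = 1 - .data$ever,
        age_band = paste0(.data$lb, "-", .data$lb + 4)
      ) |>
      dplyr::select("sex", "age_band", "never", "current", "former")
    # enforce monotone non-increasing never share within each sex (required
    # for an initiation-only pathway out of the never state)
    use_prevalence <- use_prevalence |>
      dplyr::group_by(.data$sex) |>
      dplyr::mutate(
        never = cummin(.data$never),
        ever = 1 - .data$never,
        current = .data$ever * .data$current /
          pmax(.data$current + .data$former, 1e-12),
        former = .data$ever - .data$current
      ) |>
      dplyr::ungroup() |>
      dplyr::select("sex", "age_band", "never", "current", "former")

    # disease prevalence rising with age; cancers rare, stroke more common
    dis_bands <- age_bands(15, (horizon %/% 5) * 5)
    dis_lo <- band_lower(dis_bands)
    peak <- c(oral_cancer = 0.0030, pharyngeal_cancer = 0.0012,
              esophageal_cancer = 0.0015, stroke = 0.045)
    disease_prevalence <- tidyr::crossing(
      disease = st_diseases(), sex = config$sexes, lb = dis_lo
    ) |>
      dplyr::mutate(
        ramp = (pmax(.data$lb - 25, 0) / 60)^2,
        sexf = ifelse(.data$sex == "male", 1.15, 0.85),
        prevalence = peak[.data$disease] * .data$ramp * .data$sexf *
          noise(dplyr::n()),
        age_band = paste0(.data$lb, "-", .data$lb + 4)
      ) |>
      dplyr::select("disease", "sex", "age_band", "prevalence")

    population <- tidyr::crossing(sex = config$sexes, lb = lo) |>
      dplyr::mutate(
        population = round(5e6 * exp(-0.03 * (.data$lb - 15)) *
                             ifelse(.data$sex == "male", 1, 0.95)),
        age_band = paste0(.data$lb, "-", .data$lb + 4)
      ) |>
      dplyr::select("sex", "age_band", "population")

    st_bundle(
      country = country, config = config, life_table = life_table,
      use_prevalence = use_prevalence, disease_prevalence = disease_prevalence,
      population = population,
      costs = default_costs(country),
      distributions = default_distributions(country)
    )
  })
}
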