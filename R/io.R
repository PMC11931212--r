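# Bundle serialisation: one CSV per member table (long format for the
# demographic tables, natural wide format for parameter tables) plus a JSON
# config, such that read_bundle(write_bundle(b)) reproduces b exactly.

long_cols <- c("country", "sex", "age_band", "variable", "value")

#' Write a country bundle to a directory
#'
#' Emits `config.json`, `life_table.csv`, `use_prevalence.csv`,
#' `disease_prevalence.csv`, `population.csv` (long format: country, sex,
#' age_band, variable, value), `risk_set.csv`, `disability_weights.csv`,
#' `costs.csv`, `distributions.csv` (wide parameter tables), and, when the
#' bundle carries a calibrated schedule, `schedule_rates.csv` and
#' `schedule_relapse.csv`. Writing the same bundle twice produces
#' byte-identical files.
#'
#' @param bundle An [st_bundle()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) rlang::abort(paste0("cannot create directory '", dir, "'"))
  }
  cfg <- bundle$config
  jsonlite::write_json(
    list(country = bundle$country,
         discount_rate = cfg$discount_rate, horizon_age = cfg$horizon_age,
         min_risk_age = cfg$min_risk_age, psa_draws = cfg$psa_draws,
         rng_seed = cfg$rng_seed, entry_bands = cfg$entry_bands,
         sexes = cfg$sexes, former_split = cfg$former_split,
         no_st_mortality = cfg$no_st_mortality),
    file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  to_long <- function(d, keys) {
    d |>
      tidyr::pivot_longer(-dplyr::all_of(keys),
                          names_to = "variable", values_to = "value") |>
      dplyr::mutate(country = bundle$country, .before = 1)
  }
  readr::write_csv(
    bundle$life_table |>
      dplyr::mutate(age_band = as.character(.data$age)) |>
      dplyr::select("sex", "age_band", "q_all") |>
      to_long(c("sex", "age_band")),
    file.path(dir, "life_table.csv")
  )
  readr::write_csv(to_long(bundle$use_prevalence, c("sex", "age_band")),
                   file.path(dir, "use_prevalence.csv"))
  readr::write_csv(
    bundle$disease_prevalence |>
      tidyr::pivot_wider(names_from = "disease", values_from = "prevalence") |>
      to_long(c("sex", "age_band")),
    file.path(dir, "disease_prevalence.csv")
  )
  if (!is.null(bundle$population)) {
    readr::write_csv(to_long(bundle$population, c("sex", "age_band")),
                     file.path(dir, "population.csv"))
  }
  readr::write_csv(bundle$risk_set, file.path(dir, "risk_set.csv"))
  readr::write_csv(bundle$disability_weights, file.path(dir, "disability_weights.csv"))
  readr::write_csv(bundle$costs, file.path(dir, "costs.csv"))
  readr::write_csv(bundle$distributions, file.path(dir, "distributions.csv"))
  if (!is.null(bundle$schedule)) {
    write_schedule(bundle$schedule, file.path(dir, "schedule"))
  }
  invisible(dir)
}

read_csv_quiet <- function(path, ...) {
  if (!file.exists(path)) {
    rlang::abort(paste0("required bundle table missing: ", basename(path)))
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read a country bundle from a directory
#'
#' Inverse of [write_bundle()]; the returned bundle passes full validation and
#' equals the written one field by field.
#'
#' @param dir Directory written by [write_bundle()].
#' @return An [st_bundle()].
#' @export
read_bundle <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  if (!file.exists(cfg_path)) {
    rlang::abort(paste0("required bundle table missing: config.json in ", dir))
  }
  j <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  config <- st_config(
    discount_rate = j$discount_rate, horizon_age = j$horizon_age,
    min_risk_age = j$min_risk_age, psa_draws = j$psa_draws,
    rng_seed = j$rng_seed, entry_bands = j$entry_bands, sexes = j$sexes,
    former_split = j$former_split, no_st_mortality = j$no_st_mortality
  )

  from_long <- function(d) {
    d |>
      dplyr::select(-"country") |>
      tidyr::pivot_wider(names_from = "variable", values_from = "value")
  }
  life_table <- from_long(read_csv_quiet(
    file.path(dir, "life_table.csv"),
    col_types = readr::cols(age_band = readr::col_character())
  )) |>
    dplyr::transmute(sex = .data$sex, age = as.integer(.data$age_band),
                     q_all = .data$q_all)
  use_prevalence <- from_long(read_csv_quiet(file.path(dir, "use_prevalence.csv")))
  disease_prevalence <- from_long(
    read_csv_quiet(file.path(dir, "disease_prevalence.csv"))
  ) |>
    tidyr::pivot_longer(dplyr::all_of(st_diseases()),
                        names_to = "disease", values_to = "prevalence") |>
    dplyr::select("disease", "sex", "age_band", "prevalence")
  pop_path <- file.path(dir, "population.csv")
  population <- if (file.exists(pop_path)) from_long(read_csv_quiet(pop_path))

  schedule <- if (file.exists(file.path(dir, "schedule_rates.csv"))) {
    read_schedule(file.path(dir, "schedule"))
  }

  st_bundle(
    country = j$country, config = config, life_table = life_table,
    use_prevalence = use_prevalence, disease_prevalence = disease_prevalence,
    risk_set = read_csv_quiet(file.path(dir, "risk_set.csv")),
    disability_weights = read_csv_quiet(file.path(dir, "disability_weights.csv")),
    costs = read_csv_quiet(file.path(dir, "costs.csv")),
    population = population,
    distributions = read_csv_quiet(file.path(dir, "distributions.csv")),
    schedule = schedule
  )
}
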