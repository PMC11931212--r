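# Shared fixtures, memoized so expensive calibrations run once per suite.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- fn()
  .fixtures[[key]]
}

fixture_bundle <- function() memo("bundle", function() synthetic_bundle(42))

fixture_schedule <- function() {
  memo("schedule", function() calibrate_transitions(fixture_bundle()))
}

# Bundle with every relative risk equal to 1 and all risk distributions fixed
# at 1: the null model in which smokeless tobacco is harmless.
null_bundle <- function() {
  memo("null_bundle", function() {
    b <- fixture_bundle()
    b$risk_set[, c("current", "former_0_4", "former_5_10", "former_10plus")] <- 1
    risky <- b$distributions$target == "risk"
    b$distributions$kind[risky] <- "fixed"
    b$distributions$point[risky] <- 1
    validate_bundle(b)
  })
}

null_schedule <- function() {
  memo("null_schedule", function() calibrate_transitions(null_bundle()))
}

# Reduced bundle (4 entry bands, horizon 59) for fast end-to-end command tests.
small_bundle <- function(seed = 3) {
  synthetic_bundle(
    seed,
    config = st_config(horizon_age = 59, entry_bands = age_bands(15, 30),
                       rng_seed = as.integer(seed))
  )
}

# Minimal hand-built bundle: two entry bands with prescribed never/current
# shares and a flat life table, for closed-form calibration checks.
two_band_bundle <- function(never = c(0.8, 0.7), former = c(0, 0), q = 0) {
  cfg <- st_config(horizon_age = 35, min_risk_age = 35,
                   entry_bands = c("15-19", "20-24"), sexes = "male")
  life <- tibble::tibble(sex = "male", age = 15:35, q_all = q)
  use <- tibble::tibble(
    sex = "male", age_band = cfg$entry_bands,
    never = never, former = former, current = 1 - never - former
  )
  dis <- tidyr::crossing(disease = st_diseases(), sex = "male",
                         age_band = age_bands(15, 35)) |>
    dplyr::mutate(prevalence = 0.001)
  st_bundle("testland", cfg, life, use, dis,
            costs = default_costs("india"),
            distributions = default_distributions("india"))
}

# Use-prevalence table observed from a forward cohort run: shares among the
# alive at each band lower bound. Oracle input for parameter recovery.
prevalence_from_trace <- function(trace, bands, sex) {
  lows <- band_lower(bands)
  occ <- as.matrix(trace[, st_states()])
  rows <- match(lows, trace$age)
  alive <- 1 - occ[rows, "dead"]
  tibble::tibble(
    sex = sex, age_band = bands,
    never = occ[rows, "never"] / alive,
    current = occ[rows, "current"] / alive,
    former = rowSums(occ[rows, 3:13, drop = FALSE]) / alive
  )
}
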