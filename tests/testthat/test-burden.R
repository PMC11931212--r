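test_that("discounting uses the entry cycle as time zero", {
  expect_equal(discounted_total(100, 0.03), 100)
  expect_equal(discounted_total(100, 0.15), 100)
  # independent arithmetic: 100 + 100 / 1.03
  expect_equal(discounted_total(c(100, 100), 0.03), 100 + 100 / 1.03)
  expect_equal(discounted_total(c(100, 100), 0.03), 197.0874, tolerance = 1e-6)
  expect_equal(discounted_total(c(1, 2, 3), 0), 6)
  expect_error(discounted_total(1, 1.2), "discount rate")
})

test_that("cycle cost blends incident and prevalent stroke costs", {
  costs <- default_costs("india")
  class_prev <- tidyr::crossing(disease = st_diseases(), class = st_classes()) |>
    dplyr::mutate(prevalence = ifelse(disease == "stroke", 0.01, 0),
                  population_prevalence = prevalence)
  fully_alive <- stats::setNames(c(1, rep(0, 13)), st_states())
  got <- cycle_cost(class_prev, fully_alive, costs)
  expect_equal(got, 0.01 * (0.1 * 821 + 0.9 * 82), tolerance = 1e-12)
  expect_equal(got, 1.559, tolerance = 1e-12)

  # zero prevalence -> zero cost; linearity in unit costs
  zero <- dplyr::mutate(class_prev, prevalence = 0)
  expect_equal(cycle_cost(zero, fully_alive, costs), 0)
  doubled <- dplyr::mutate(costs,
                           annual_cancer_cost = annual_cancer_cost * 2,
                           incident_stroke_cost = incident_stroke_cost * 2,
                           prevalent_stroke_cost = prevalent_stroke_cost * 2)
  expect_equal(cycle_cost(class_prev, fully_alive, doubled), 2 * got)
})

test_that("cycle YLD is prevalence times weight, additive over diseases", {
  b <- fixture_bundle()
  fully_alive <- stats::setNames(c(1, rep(0, 13)), st_states())
  one <- tidyr::crossing(disease = st_diseases(), class = st_classes()) |>
    dplyr::mutate(prevalence = ifelse(disease == "oral_cancer", 0.02, 0),
                  population_prevalence = prevalence)
  # oral cancer weight at ages 15-49 is 0.164
  expect_equal(cycle_yld(one, fully_alive, b$disability_weights, "male", 40),
               0.02 * 0.164)
  expect_equal(0.02 * 0.164, 0.00328)

  two <- dplyr::mutate(one, prevalence = ifelse(disease == "stroke", 0.05,
                                                prevalence))
  expect_equal(
    cycle_yld(two, fully_alive, b$disability_weights, "male", 40),
    0.02 * 0.164 + 0.05 * 0.210
  )
  none <- dplyr::mutate(one, prevalence = 0)
  expect_equal(cycle_yld(none, fully_alive, b$disability_weights, "female", 75), 0)
})

test_that("class disease prevalence collapses to the population value without risk", {
  b <- fixture_bundle()
  shares <- c(0.5, 0.3, 0.1, 0.05, 0.05)
  # age below the no-effect threshold: every class equals the population value
  cp <- cycle_disease_burden(b, "male", 30, shares)
  expect_equal(cp$prevalence, cp$population_prevalence)
  # above it, conservation holds but classes differ
  cp2 <- cycle_disease_burden(b, "male", 60, shares)
  by_d <- split(cp2, cp2$disease)
  for (d in by_d) {
    expect_lt(abs(sum(shares * d$prevalence) - d$population_prevalence[1]), 1e-12)
  }
  expect_gt(max(abs(cp2$prevalence - cp2$population_prevalence)), 0)
})

test_that("a harmless exposure yields exactly zero attributable burden", {
  b <- null_bundle()
  sched <- null_schedule()
  for (co in list(c("male", "15-19"), c("female", "45-49"), c("male", "70-74"))) {
    res <- burden_for_cohort(b, co[1], co[2], sched)
    expect_equal(res$d_ly, 0, tolerance = 1e-12)
    expect_equal(res$d_yld, 0, tolerance = 1e-12)
    expect_equal(res$d_cost, 0, tolerance = 1e-12)
    expect_equal(res$dalys_averted, 0, tolerance = 1e-12)
  }
})

test_that("raising current-user mortality risk increases life years gained", {
  b <- fixture_bundle()
  sched <- fixture_schedule()
  d_ly <- purrr::map_dbl(c(1.25, 1.6, 2.2), function(rr) {
    bi <- b
    bi$risk_set$current[bi$risk_set$outcome == "mortality"] <- rr
    burden_for_cohort(bi, "male", "35-39", sched)$d_ly
  })
  expect_true(all(diff(d_ly) > 0))
})

test_that("burden results are deterministic", {
  b <- fixture_bundle()
  r1 <- burden_for_cohort(b, "female", "25-29", fixture_schedule())
  r2 <- burden_for_cohort(b, "female", "25-29", fixture_schedule())
  expect_identical(tidy(r1), tidy(r2))
})

test_that("discounted burden is smaller than undiscounted burden", {
  b <- fixture_bundle()
  sched <- fixture_schedule()
  b0 <- b
  b0$config$discount_rate <- 0
  r3 <- burden_for_cohort(b, "male", "15-19", sched)
  r0 <- burden_for_cohort(b0, "male", "15-19", sched)
  sc3 <- r3$scenarios; sc0 <- r0$scenarios
  expect_true(all(sc3$cost < sc0$cost))
  expect_true(all(sc3$life_years < sc0$life_years))
  expect_lt(r3$d_cost, r0$d_cost)
})

test_that("entry-state attribution decomposes the full attributable cost", {
  b <- fixture_bundle()
  sched <- fixture_schedule()
  for (co in list(c("male", "15-19"), c("female", "50-54"))) {
    full <- burden_for_cohort(b, co[1], co[2], sched)
    at <- attribute_by_entry_state(b, co[1], co[2], sched)
    expect_lt(abs(sum(at$weight * at$attributable_cost) - full$d_cost), 1e-9)
    expect_equal(sum(at$share), 1, tolerance = 1e-9)
  }
  # a young cohort with positive initiation: those not yet using bear burden
  at_young <- attribute_by_entry_state(b, "male", "15-19", sched)
  expect_gt(at_young$share[at_young$entry_state == "never"], 0)
})

test_that("attribution shares are undefined, not NaN, when nothing is attributable", {
  b <- null_bundle()
  at <- attribute_by_entry_state(b, "male", "40-44", null_schedule())
  expect_true(all(is.na(at$share)))
  expect_false(any(is.nan(at$share)))
})

test_that("country aggregation is additive and scales with population", {
  b <- small_bundle()
  sched <- calibrate_transitions(b)
  agg <- aggregate_country(b, sched)
  tot <- attr(agg, "totals")
  expect_equal(tot$total_cost_saved, sum(agg$total_cost_saved))
  expect_equal(agg$total_cost_saved, agg$cost_saved * agg$population)

  b2 <- b
  b2$population$population <- b2$population$population * 2
  agg2 <- aggregate_country(b2, sched)
  expect_equal(attr(agg2, "totals")$total_cost_saved, 2 * tot$total_cost_saved,
               tolerance = 1e-12)

  b0 <- b
  b0$population$population <- 0
  agg0 <- aggregate_country(b0, sched)
  expect_equal(attr(agg0, "totals")$total_cost_saved, 0)

  b_miss <- b
  b_miss$population <- NULL
  expect_error(aggregate_country(b_miss, sched), "population")
})
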