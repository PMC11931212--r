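test_that("transition matrix rows encode death-first ordering and tunnel advance", {
  rl <- default_relapse(0, 0, 0)

  # no mortality, initiation only
  P <- build_transition_matrix(0.1, 0, rl, rep(0, 5))
  expect_equal(unname(P["never", c("never", "current")]), c(0.9, 0.1))
  expect_equal(sum(P["never", c("never", "current")]), 1)

  # mortality only: each living row sends q to dead, the rest to its successor
  q <- 0.07
  P <- build_transition_matrix(0, 0, rl, rep(q, 5))
  expect_equal(unname(P[, "dead"]), c(rep(q, 13), 1))
  expect_equal(unname(diag(P)[c(1, 2, 13)]), rep(1 - q, 3))
  for (t in 1:10) {
    to <- if (t < 10) paste0("former_", t + 1) else "former_long"
    expect_equal(P[paste0("former_", t), to], 1 - q)
  }

  # relapse pulls tunnel occupants back to current before advancing
  rl2 <- default_relapse(0.2, 1, 0.05)
  P <- build_transition_matrix(0, 0, rl2, rep(0, 5))
  expect_equal(unname(P["former_3", c("current", "former_4")]), c(0.2, 0.8))
  expect_equal(unname(P["former_long", c("current", "former_long")]),
               c(0.05, 0.95))

  expect_error(build_transition_matrix(1.2, 0, rl, rep(0, 5)),
               "initiation")
  expect_error(build_transition_matrix(0, 0, rl, c(0, -0.1, 0, 0, 0)),
               "q_current")
})

test_that("every assembled matrix over the full age grid is row-stochastic", {
  b <- fixture_bundle()
  sched <- fixture_schedule()
  lk <- stburden:::schedule_lookup(sched, b$config$horizon_age)
  worst <- 0
  for (sx in b$config$sexes) {
    lt <- b$life_table[b$life_table$sex == sx, ]
    for (a in 15:b$config$horizon_age) {
      shares <- c(0.4, 0.3, 0.1, 0.1, 0.1)
      mult <- effective_multipliers(b$risk_set, "mortality", a)
      q <- status_specific_rate(lt$q_all[lt$age == a], shares, mult)
      P <- build_transition_matrix(lk[[sx]]$initiation[a - 14],
                                   lk[[sx]]$quit[a - 14], sched$relapse, q)
      worst <- max(worst, abs(rowSums(P) - 1))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("initiation calibration matches the zero-mortality closed form", {
  # never share 0.80 -> 0.70 over one band with no deaths:
  # 0.8 (1 - i)^5 = 0.7, solved independently of the calibrator
  i_closed <- 1 - (0.7 / 0.8)^(1 / 5)
  expect_equal(i_closed, 0.026353, tolerance = 1e-5)

  b <- two_band_bundle(never = c(0.8, 0.7))
  rates <- calibrate_initiation(b, "male")
  expect_equal(rates$initiation[rates$age %in% 15:19], rep(i_closed, 5),
               tolerance = 1e-10)

  # flat never share, uniform mortality: no initiation
  b2 <- two_band_bundle(never = c(0.8, 0.8), q = 0.01)
  rates2 <- calibrate_initiation(b2, "male")
  expect_equal(rates2$initiation, rep(0, nrow(rates2)), tolerance = 1e-10)

  # rising never share is unreachable: clamped to 0 with a warning
  b3 <- two_band_bundle(never = c(0.7, 0.8))
  expect_warning(rates3 <- calibrate_initiation(b3, "male"), "clamped")
  expect_equal(max(rates3$initiation), 0)
})

test_that("quit calibration is zero when no former users are observed", {
  b <- two_band_bundle(never = c(0.8, 0.7), former = c(0, 0))
  rates <- calibrate_quit(b, "male", initiation = 0.026334,
                          relapse = default_relapse(0, 0, 0))
  expect_equal(rates$quit, rep(0, nrow(rates)), tolerance = 1e-10)
})

test_that("calibration recovers the schedule that generated the prevalence", {
  b <- fixture_bundle()
  relapse <- default_relapse()
  bands <- b$config$entry_bands
  # known generating schedule: band-constant, age-varying rates
  nb <- length(bands)
  i_true <- seq(0.030, 0.008, length.out = nb - 1)
  c_true <- seq(0.020, 0.060, length.out = nb - 1)
  per_age <- rep(seq_len(nb - 1), each = 5)
  gen <- st_schedule(
    purrr::map_dfr(b$config$sexes, function(sx) tibble::tibble(
      sex = sx, age = 15:(14 + 5 * (nb - 1)),
      initiation = i_true[per_age], quit = c_true[per_age]
    )),
    relapse
  )
  # generate banded prevalence with the cohort engine as the oracle
  b_gen <- b
  b_gen$use_prevalence <- purrr::map_dfr(b$config$sexes, function(sx) {
    tr <- run_cohort(b, sx, bands[1], gen, scenario = "status_quo")
    prevalence_from_trace(tr, bands, sx)
  })
  b_gen <- validate_bundle(b_gen)

  sched <- calibrate_transitions(b_gen, relapse)
  for (sx in b$config$sexes) {
    got <- sched$rates[sched$rates$sex == sx, ]
    ages <- 15:(14 + 5 * (nb - 1))
    expect_equal(got$initiation[match(ages, got$age)], i_true[per_age],
                 tolerance = 1e-6)
    expect_equal(got$quit[match(ages, got$age)], c_true[per_age],
                 tolerance = 1e-6)
  }

  # and the calibrated model reproduces the observed table
  pp <- projected_prevalence(b_gen, sched)
  expect_lt(max(abs(pp$projected - pp$observed)), 0.005)
})

test_that("doubling relapse raises the calibrated quit probability everywhere", {
  b <- fixture_bundle()
  s1 <- calibrate_transitions(b, default_relapse(0.05, 0.6))
  s2 <- calibrate_transitions(b, default_relapse(0.10, 0.6))
  expect_true(all(s2$rates$quit >= s1$rates$quit - 1e-9))
  expect_gt(mean(s2$rates$quit), mean(s1$rates$quit))
})

test_that("schedules survive a CSV round trip", {
  sched <- fixture_schedule()
  stem <- file.path(withr::local_tempdir(), "sched")
  write_schedule(sched, stem)
  back <- read_schedule(stem)
  expect_equal(back$rates, sched$rates)
  expect_equal(back$relapse$prob, sched$relapse$prob)
  expect_equal(back$relapse$tail, sched$relapse$tail)
})

test_that("schedule construction rejects invalid probabilities", {
  expect_error(st_schedule(tibble::tibble(sex = "male", age = 15,
                                          initiation = -0.1, quit = 0)),
               "\\[0, 1\\]")
  expect_error(
    st_schedule(tibble::tibble(sex = "male", age = 15, initiation = 0, quit = 0),
                list(prob = seq(0.01, 0.1, length.out = 10), tail = 0)),
    "non-increasing"
  )
})
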