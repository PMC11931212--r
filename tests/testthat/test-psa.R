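test_that("parameter sampling matches distribution closed forms", {
  expect_equal(sample_parameter("fixed", NA, NA, 1.25), 1.25)
  withr::with_seed(101, {
    beta_draws <- replicate(1e5, sample_parameter("beta", 8.20, 41.80))
    # beta mean alpha / (alpha + beta) = 0.164
    expect_lt(abs(mean(beta_draws) - 0.164), 0.002)

    ln_draws <- replicate(1e5, sample_parameter("lognormal", 0.22, 0.07))
    # lognormal median = exp(mu)
    expect_lt(abs(stats::median(ln_draws) - exp(0.22)), 0.01 * exp(0.22))

    g_draws <- replicate(1e5, sample_parameter("gamma", 100, 21.64))
    # gamma mean = shape * scale
    expect_lt(abs(mean(g_draws) - 2164), 3 * 216.4 / sqrt(1e5) * sqrt(100))
  })
  expect_error(sample_parameter("lognormal", 0.2, -1), "positive")
  expect_error(sample_parameter("beta", 0, 45), "positive")
  expect_error(sample_parameter("uniform", 0, 1), "unknown distribution")
})

test_that("perturbed bundles are reproducible and structurally valid", {
  b <- fixture_bundle()
  d1 <- withr::with_seed(9, draw_parameter_set(b))
  d2 <- withr::with_seed(9, draw_parameter_set(b))
  expect_equal(d1$risk_set, d2$risk_set)
  expect_equal(d1$disability_weights, d2$disability_weights)
  expect_equal(d1$costs, d2$costs)

  withr::with_seed(31, {
    for (k in 1:100) {
      p <- draw_parameter_set(b)
      m <- as.matrix(p$risk_set[, c("current", "former_0_4",
                                    "former_5_10", "former_10plus")])
      expect_true(all(m[, 1] >= m[, 2] & m[, 2] >= m[, 3] & m[, 3] >= m[, 4]))
      expect_true(all(p$risk_set$former_10plus == 1))
      expect_true(all(p$disability_weights$weight > 0 &
                        p$disability_weights$weight < 1))
      expect_lte(p$costs$prevalent_stroke_cost, p$costs$incident_stroke_cost)
    }
  })
})

test_that("all-fixed distributions leave the bundle unchanged", {
  b <- fixture_bundle()
  b$distributions$kind <- "fixed"
  p <- withr::with_seed(1, draw_parameter_set(b))
  expect_equal(p$risk_set, b$risk_set)
  expect_equal(p$disability_weights, b$disability_weights)
  expect_equal(p$costs, b$costs)
})

test_that("unconstrained draw means match their distribution means", {
  b <- fixture_bundle()
  n <- 1500
  draws <- withr::with_seed(77, purrr::map(seq_len(n), function(k) {
    p <- draw_parameter_set(b)
    c(weight = p$disability_weights$weight[
        p$disability_weights$disease == "oral_cancer" &
          p$disability_weights$sex == "male" &
          p$disability_weights$age_group == "15-49"],
      cancer_cost = p$costs$annual_cancer_cost,
      frac = p$costs$incident_stroke_fraction)
  }))
  draws <- do.call(rbind, draws)
  # analytic means and 3 Monte-Carlo standard errors
  mean_w <- 8.2 / 50
  se_w <- sqrt(mean_w * (1 - mean_w) / 51) / sqrt(n)
  expect_lt(abs(mean(draws[, "weight"]) - mean_w), 3 * se_w)
  se_c <- (2164 / 10) / sqrt(n)
  expect_lt(abs(mean(draws[, "cancer_cost"]) - 2164), 3 * se_c)
  mean_f <- 5 / 50
  se_f <- sqrt(mean_f * (1 - mean_f) / 51) / sqrt(n)
  expect_lt(abs(mean(draws[, "frac"]) - mean_f), 3 * se_f)
})

test_that("the PSA is reproducible under a fixed seed", {
  b <- small_bundle()
  sched <- calibrate_transitions(b)
  co <- tibble::tibble(sex = "male", entry_band = "15-19")
  p1 <- run_psa(b, sched, cohorts = co, n_draws = 10, seed = 123)
  p2 <- run_psa(b, sched, cohorts = co, n_draws = 10, seed = 123)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$summary, p2$summary)
  expect_equal(glance(p1)$n_draws, 10L)
  expect_equal(nrow(p1$draws), 10 * 4)
})

test_that("fixed distributions collapse the credible interval to the point", {
  b <- small_bundle()
  b$distributions$kind <- "fixed"
  sched <- calibrate_transitions(b)
  co <- tibble::tibble(sex = "female", entry_band = "20-24")
  p <- run_psa(b, sched, cohorts = co, n_draws = 1, seed = 4)
  expect_equal(p$summary$lower, p$summary$point, tolerance = 1e-12)
  expect_equal(p$summary$upper, p$summary$point, tolerance = 1e-12)
  expect_equal(p$summary$mean, p$summary$point, tolerance = 1e-12)
})

test_that("a harmless exposure propagates to an all-zero credible interval", {
  b <- null_bundle()
  sched <- null_schedule()
  co <- tibble::tibble(sex = "male", entry_band = "30-34")
  p <- run_psa(b, sched, cohorts = co, n_draws = 15, seed = 2)
  expect_equal(max(abs(p$draws$value)), 0)
  expect_equal(p$summary$lower, rep(0, 4))
  expect_equal(p$summary$upper, rep(0, 4))
})

test_that("the point estimate falls inside the packaged-fixture credible interval", {
  b <- small_bundle()
  sched <- calibrate_transitions(b)
  co <- tibble::tibble(sex = "male", entry_band = "15-19")
  p <- run_psa(b, sched, cohorts = co, n_draws = 60, seed = 11)
  s <- p$summary
  expect_true(all(s$point >= s$lower & s$point <= s$upper))
})

test_that("tidy and glance summarise PSA objects", {
  b <- small_bundle()
  b$distributions$kind <- "fixed"
  sched <- calibrate_transitions(b)
  p <- run_psa(b, sched, cohorts = tibble::tibble(sex = "male",
                                                  entry_band = "15-19"),
               n_draws = 2, seed = 1)
  expect_named(tidy(p), c("sex", "entry_band", "output", "point", "mean",
                          "lower", "upper"))
  g <- glance(p)
  expect_equal(g$n_cohorts, 1L)
  expect_equal(g$n_outputs, 4L)
})
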