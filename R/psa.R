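# Probabilistic sensitivity analysis: sample every uncertain parameter from
# its assigned distribution, rerun the deterministic pipeline per draw, and
# summarise 95% credible intervals from the empirical percentiles.

#' Sample one parameter from its uncertainty distribution
#'
#' Lognormal draws are `exp(rnorm(mean_log, se_log))`; beta draws use
#' `rbeta(alpha, beta)`; gamma draws use `rgamma(shape, scale)`; `fixed`
#' returns the point estimate. Consumes the current RNG stream, so draws are
#' reproducible under a fixed generator state.
#'
#' @param kind `"lognormal"`, `"beta"`, `"gamma"` or `"fixed"`.
#' @param par1,par2 Distribution parameters (see [default_distributions()]).
#' @param point Point estimate, returned for `"fixed"`.
#' @return One numeric draw.
#' @export
sample_parameter <- function(kind, par1, par2, point = NA_real_) {
  switch(kind,
    lognormal = {
      if (par2 <= 0) rlang::abort("lognormal se must be positive")
      exp(stats::rnorm(1, par1, par2))
    },
    beta = {
      if (par1 <= 0 || par2 <= 0) rlang::abort("beta parameters must be positive")
      stats::rbeta(1, par1, par2)
    },
    gamma = {
      if (par1 <= 0 || par2 <= 0) rlang::abort("gamma parameters must be positive")
      stats::rgamma(1, shape = par1, scale = par2)
    },
    fixed = point,
    rlang::abort(paste0("unknown distribution kind '", kind, "'"))
  )
}

# Draw an outcome's relative-risk strata jointly, resampling until the
# structural ordering current >= former_0_4 >= former_5_10 >= 1 holds.
draw_rr_strata <- function(rows, max_tries = 1000) {
  stratum_order <- c("current", "former_0_4", "former_5_10")
  rows <- rows[match(stratum_order, rows$stratum), ]
  resampled <- 0L
  for (k in seq_len(max_tries)) {
    draw <- purrr::pmap_dbl(rows[, c("kind", "par1", "par2", "point")],
                            function(kind, par1, par2, point) {
                              sample_parameter(kind, par1, par2, point)
                            })
    if (all(diff(draw) <= 0) && draw[3] >= 1) {
      return(list(draw = stats::setNames(draw, stratum_order),
                  resampled = resampled))
    }
    resampled <- resampled + 1L
  }
  # fall back to an ordered, floored draw rather than aborting the PSA
  draw <- sort(pmax(draw, 1), decreasing = TRUE)
  list(draw = stats::setNames(draw, stratum_order), resampled = resampled)
}

#' Draw a perturbed parameter set
#'
#' Returns a copy of the bundle with every uncertain parameter replaced by one
#' draw from its distribution: relative risks of mortality and disease per
#' exposure stratum, disability weights, disease unit costs and the
#' incident-stroke fraction. Structural constraints are re-enforced after
#' sampling: the 10+-years multiplier stays exactly 1, and the former strata
#' are resampled when a draw violates the monotone ordering (the number of
#' resampled outcomes is recorded in `attr(, "n_resampled")`). Transition
#' probabilities are held at their calibrated values.
#'
#' @param bundle An [st_bundle()].
#' @return A perturbed `st_bundle` (re-validated).
#' @export
draw_parameter_set <- function(bundle) {
  di <- bundle$distributions
  out <- bundle
  n_resampled <- 0L

  rr <- di[di$target == "risk", ]
  for (oc in unique(rr$outcome)) {
    d <- draw_rr_strata(rr[rr$outcome == oc, ])
    n_resampled <- n_resampled + d$resampled
    i <- match(oc, out$risk_set$outcome)
    out$risk_set$current[i] <- d$draw[["current"]]
    out$risk_set$former_0_4[i] <- d$draw[["former_0_4"]]
    out$risk_set$former_5_10[i] <- d$draw[["former_5_10"]]
    out$risk_set$former_10plus[i] <- 1
  }

  dw <- di[di$target == "weight", ]
  for (k in seq_len(nrow(dw))) {
    row <- dw[k, ]
    val <- sample_parameter(row$kind, row$par1, row$par2, row$point)
    sel <- out$disability_weights$disease == row$outcome &
      out$disability_weights$age_group == row$stratum
    out$disability_weights$weight[sel] <- val
  }

  co <- di[di$target == "cost", ]
  for (k in seq_len(nrow(co))) {
    row <- co[k, ]
    val <- sample_parameter(row$kind, row$par1, row$par2, row$point)
    out$costs[[switch(row$outcome,
      cancer = "annual_cancer_cost",
      incident_stroke = "incident_stroke_cost",
      prevalent_stroke = "prevalent_stroke_cost"
    )]] <- val
  }
  # keep the prevalent <= incident structural constraint
  if (out$costs$prevalent_stroke_cost > out$costs$incident_stroke_cost) {
    out$costs$prevalent_stroke_cost <- out$costs$incident_stroke_cost
  }

  fr <- di[di$target == "fraction", ]
  if (nrow(fr) == 1) {
    out$costs$incident_stroke_fraction <-
      sample_parameter(fr$kind, fr$par1, fr$par2, fr$point)
  }

  out <- validate_bundle(out)
  attr(out, "n_resampled") <- n_resampled
  out
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws `n_draws` independent parameter sets, reruns the cohort burden
#' pipeline for each requested cohort per draw (transition schedules held at
#' their calibrated values), and summarises each output by the mean of draws
#' and the 2.5th/97.5th empirical percentiles (95% credible interval). The
#' point estimate comes from an unperturbed run. Fully reproducible given the
#' seed.
#'
#' @param bundle An [st_bundle()].
#' @param schedule An [st_schedule()]; defaults to the bundle's.
#' @param cohorts Tibble (`sex`, `entry_band`) of cohorts to evaluate;
#'   default: every entry band for every sex.
#' @param n_draws Number of Monte Carlo draws (the bundle config's `psa_draws`
#'   by default).
#' @param seed Integer seed (the bundle config's `rng_seed` by default).
#' @return A list of class `st_psa` with `draws` (tibble: draw, sex,
#'   entry_band, output, value), `summary` (tibble: sex, entry_band, output,
#'   point, mean, lower, upper), `n_draws` and `seed`.
#' @export
run_psa <- function(bundle, schedule = bundle$schedule, cohorts = NULL,
                    n_draws = bundle$config$psa_draws,
                    seed = bundle$config$rng_seed) {
  if (is.null(schedule)) {
    rlang::abort("no schedule supplied and bundle has none; run calibrate_transitions()")
  }
  if (n_draws < 1) rlang::abort("n_draws must be >= 1")
  if (is.null(cohorts)) {
    cohorts <- tidyr::crossing(sex = bundle$config$sexes,
                               entry_band = bundle$config$entry_bands)
  }

  eval_bundle <- function(b) {
    purrr::pmap_dfr(cohorts, function(sex, entry_band) {
      res <- burden_for_cohort(b, sex, entry_band, schedule)
      tibble::tibble(
        sex = sex, entry_band = entry_band,
        output = c("life_years_gained", "yld_averted", "dalys_averted",
                   "cost_saved"),
        value = c(res$d_ly, res$d_yld, res$dalys_averted, res$d_cost)
      )
    })
  }

  point <- eval_bundle(bundle)
  draws <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(n_draws), function(k) {
      pb <- tryCatch(
        draw_parameter_set(bundle),
        error = function(e) {
          rlang::abort(paste0("PSA draw ", k, " (seed ", seed, ") failed: ",
                              conditionMessage(e)))
        }
      )
      dplyr::mutate(eval_bundle(pb), draw = k, .before = 1)
    })
  })

  summary <- draws |>
    dplyr::group_by(.data$sex, .data$entry_band, .data$output) |>
    dplyr::summarise(
      mean = mean(.data$value),
      lower = unname(stats::quantile(.data$value, 0.025, type = 7)),
      upper = unname(stats::quantile(.data$value, 0.975, type = 7)),
      .groups = "drop"
    ) |>
    dplyr::left_join(dplyr::rename(point, point = "value"),
                     by = c("sex", "entry_band", "output")) |>
    dplyr::select("sex", "entry_band", "output",
                  "point", "mean", "lower", "upper")

  structure(list(draws = draws, summary = summary,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "st_psa")
}

#' @export
print.st_psa <- function(x, ...) {
  cat("<st_psa>", x$n_draws, "draws, seed", x$seed, "\n")
  print(x$summary, n = 12)
  invisible(x)
}

#' Tidy PSA results
#'
#' @param x An `st_psa`.
#' @param ... Unused.
#' @return The summary tibble: one row per (sex, entry band, output) with
#'   point estimate, mean of draws and the 95% credible interval.
#' @export
tidy.st_psa <- function(x, ...) x$summary

#' One-line PSA summary
#'
#' @param x An `st_psa`.
#' @param ... Unused.
#' @return A one-row tibble with draw count, seed and cohort count.
#' @export
glance.st_psa <- function(x, ...) {
  tibble::tibble(
    n_draws = x$n_draws, seed = x$seed,
    n_cohorts = nrow(dplyr::distinct(x$summary, .data$sex, .data$entry_band)),
    n_outputs = length(unique(x$summary$output))
  )
}
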