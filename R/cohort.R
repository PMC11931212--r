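# Cohort engine: run one entering age-sex cohort forward in annual cycles to
# the horizon under a named scenario, producing the full state-occupancy trace.

#' Initial state vector for an entering cohort
#'
#' Distributes an entering cohort over the 14 model states from the observed
#' never/current/former use prevalence at its entry band. Former-user mass is
#' allocated across the years-since-quit tunnel by the split rule: the default
#' spreads it uniformly over tunnel years 1-10; `"long"` places it all in the
#' 10+ state. A numeric vector of 11 non-negative weights (tunnel years 1-10
#' plus 10+) may be given instead.
#'
#' @param use_prevalence Use-prevalence tibble from an [st_bundle()].
#' @param sex `"male"` or `"female"`.
#' @param entry_band Entry band label, e.g. `"15-19"`.
#' @param former_split `"uniform10"`, `"long"`, or an 11-weight numeric vector.
#' @return Named numeric vector over [st_states()] summing to 1.
#' @export
initial_state_vector <- function(use_prevalence, sex, entry_band,
                                 former_split = "uniform10") {
  row <- use_prevalence[use_prevalence$sex == sex &
                          use_prevalence$age_band == entry_band, ]
  if (nrow(row) != 1) {
    rlang::abort(paste0("use prevalence has no row for ", sex,
                        " band ", entry_band))
  }
  if (is.character(former_split)) {
    w <- switch(former_split,
      uniform10 = c(rep(0.1, 10), 0),
      long = c(rep(0, 10), 1),
      rlang::abort(paste0("unknown former_split rule '", former_split, "'"))
    )
  } else {
    if (length(former_split) != 11 || any(former_split < 0) ||
        sum(former_split) <= 0) {
      rlang::abort("numeric former_split must be 11 non-negative weights")
    }
    w <- former_split / sum(former_split)
  }
  v <- c(row$never, row$current, row$former * w, 0)
  stats::setNames(v, st_states())
}

# Core forward run under the status-quo scenario. Returns the occupancy
# matrix, alive exposure shares, class-specific mortality per cycle and the
# per-cycle transition matrices (so sub-cohorts and counterfactuals can reuse
# exactly the same dynamics).
engine_run <- function(bundle, sex, entry_band, schedule, v0 = NULL) {
  cfg <- bundle$config
  entry_age <- band_lower(entry_band)
  ages <- entry_age:cfg$horizon_age
  n <- length(ages)
  lt <- bundle$life_table[bundle$life_table$sex == sex, ]
  q_all <- lt$q_all[match(ages, lt$age)]
  lk <- schedule_lookup(schedule, cfg$horizon_age)[[sex]]
  if (is.null(lk)) rlang::abort(paste0("schedule has no rates for sex '", sex, "'"))
  if (is.null(v0)) {
    v0 <- initial_state_vector(bundle$use_prevalence, sex, entry_band,
                               cfg$former_split)
  }

  occ <- matrix(0, n, 14, dimnames = list(NULL, st_states()))
  shares <- matrix(0, n, 5, dimnames = list(NULL, st_classes()))
  q_class <- matrix(0, n, 5, dimnames = list(NULL, st_classes()))
  P_list <- vector("list", max(n - 1, 0))
  occ[1, ] <- v0
  for (t in seq_len(n)) {
    a <- ages[t]
    shares[t, ] <- class_shares(occ[t, ])
    mult <- effective_multipliers(bundle$risk_set, "mortality", a,
                                  cfg$min_risk_age)
    q_class[t, ] <- status_specific_rate(q_all[t], shares[t, ], mult)
    if (t < n) {
      k <- a - 14
      P <- build_transition_matrix(lk$initiation[k], lk$quit[k],
                                   schedule$relapse, q_class[t, ])
      P_list[[t]] <- P
      occ[t + 1, ] <- as.numeric(occ[t, ] %*% P)
    }
  }
  list(ages = ages, occ = occ, shares = shares, q_class = q_class,
       q_all = q_all, P_list = P_list, sex = sex, entry_band = entry_band)
}

# Propagate an alternative initial vector through stored transition matrices.
propagate <- function(v0, P_list, n) {
  occ <- matrix(0, n, 14, dimnames = list(NULL, st_states()))
  occ[1, ] <- v0
  for (t in seq_len(n - 1)) occ[t + 1, ] <- as.numeric(occ[t, ] %*% P_list[[t]])
  occ
}

engine_to_trace <- function(eng, scenario) {
  out <- tibble::as_tibble(eng$occ)
  out <- dplyr::mutate(out,
    cycle = seq_along(eng$ages) - 1L, age = eng$ages,
    alive = 1 - .data$dead, .before = 1
  )
  attr(out, "sex") <- eng$sex
  attr(out, "entry_band") <- eng$entry_band
  attr(out, "scenario") <- scenario
  attr(out, "shares") <- eng$shares
  attr(out, "q_class") <- eng$q_class
  attr(out, "q_all") <- eng$q_all
  class(out) <- c("st_trace", class(out))
  out
}

#' Run one cohort to the horizon
#'
#' Advances an entering age-sex cohort through annual cycles from its entry
#' age to the horizon. Under `"status_quo"` the cohort starts from the
#' observed use-state distribution and, each cycle, the life-table mortality
#' at that age is apportioned across exposure classes from the cohort's own
#' current alive shares (so the share-weighted death probability always equals
#' the life table). Under `"no_st"` the entire cohort is a never user, no one
#' initiates, and mortality is the never-user mortality implied by the
#' status-quo apportionment at each cycle (or the raw life-table value when
#' the bundle config sets `no_st_mortality = "population"`).
#'
#' @param bundle An [st_bundle()].
#' @param sex `"male"` or `"female"`.
#' @param entry_band Entry band label.
#' @param schedule An [st_schedule()]; defaults to the bundle's calibrated
#'   schedule.
#' @param scenario `"status_quo"` or `"no_st"`.
#' @return A tibble of class `st_trace`: one row per cycle with columns
#'   `cycle`, `age`, `alive` and the 14 state occupancies. Rows sum to 1.
#' @export
run_cohort <- function(bundle, sex, entry_band, schedule = bundle$schedule,
                       scenario = c("status_quo", "no_st")) {
  scenario <- match.arg(scenario)
  if (is.null(schedule)) {
    rlang::abort("no schedule supplied and bundle has none; run calibrate_transitions()")
  }
  eng <- engine_run(bundle, sex, entry_band, schedule)
  if (scenario == "status_quo") return(engine_to_trace(eng, scenario))

  n <- length(eng$ages)
  q_never <- if (bundle$config$no_st_mortality == "never") {
    eng$q_class[, "never"]
  } else {
    eng$q_all
  }
  occ <- matrix(0, n, 14, dimnames = list(NULL, st_states()))
  occ[1, 1] <- 1
  for (t in seq_len(n - 1)) {
    occ[t + 1, 1] <- occ[t, 1] * (1 - q_never[t])
    occ[t + 1, 14] <- occ[t, 14] + occ[t, 1] * q_never[t]
  }
  eng2 <- eng
  eng2$occ <- occ
  eng2$shares <- matrix(rep(c(1, 0, 0, 0, 0), each = n), n, 5,
                        dimnames = list(NULL, st_classes()))
  eng2$q_class <- matrix(rep(q_never, 5), n, 5,
                         dimnames = list(NULL, st_classes()))
  engine_to_trace(eng2, scenario)
}

#' Decompose a cohort by state at entry
#'
#' Runs the full status-quo cohort once to fix the per-cycle transition
#' matrices, then propagates three sub-cohorts — those who are never, current
#' and former users at entry — through the identical matrices. Because the
#' Markov update is linear, the entry-prevalence-weighted sum of the three
#' sub-traces reconstructs the full trace.
#'
#' @inheritParams run_cohort
#' @return A list with `full` (the full `st_trace`), `weights` (named entry
#'   shares) and `traces` (named list of sub-cohort `st_trace`s, each starting
#'   from mass 1 within its group; groups with zero entry mass are omitted).
#' @export
run_subcohorts_by_initial_state <- function(bundle, sex, entry_band,
                                            schedule = bundle$schedule) {
  if (is.null(schedule)) {
    rlang::abort("no schedule supplied and bundle has none; run calibrate_transitions()")
  }
  eng <- engine_run(bundle, sex, entry_band, schedule)
  n <- length(eng$ages)
  v0 <- eng$occ[1, ]
  groups <- list(
    never = c(1, rep(0, 13)),
    current = c(0, 1, rep(0, 12)),
    former = {
      f <- v0; f[c(1, 2, 14)] <- 0
      if (sum(f) > 0) f / sum(f) else NULL
    }
  )
  weights <- c(never = v0[[1]], current = v0[[2]], former = sum(v0[3:13]))
  traces <- purrr::imap(groups, function(g, nm) {
    if (is.null(g) || weights[[nm]] == 0) return(NULL)
    eng_g <- eng
    eng_g$occ <- propagate(g, eng$P_list, n)
    engine_to_trace(eng_g, "status_quo")
  })
  traces <- purrr::compact(traces)
  list(full = engine_to_trace(eng, "status_quo"),
       weights = weights, traces = traces)
}

#' Check mortality and disease-prevalence conservation along a run
#'
#' Recomputes, at every cycle of a status-quo run, the share-weighted
#' status-specific mortality against the life-table value and the
#' share-weighted status-specific prevalence of each disease against the input
#' population prevalence.
#'
#' @inheritParams run_cohort
#' @return Tibble (`cycle`, `age`, `quantity`, `error`) of absolute
#'   conservation errors.
#' @export
conservation_check <- function(bundle, sex, entry_band,
                               schedule = bundle$schedule) {
  eng <- engine_run(bundle, sex, entry_band, schedule)
  cfg <- bundle$config
  dp <- bundle$disease_prevalence[bundle$disease_prevalence$sex == sex, ]
  purrr::map_dfr(seq_along(eng$ages), function(t) {
    a <- eng$ages[t]
    mort_err <- abs(sum(eng$shares[t, ] * eng$q_class[t, ]) - eng$q_all[t])
    dis <- purrr::map_dbl(st_diseases(), function(d) {
      p <- dp$prevalence[dp$disease == d & dp$age_band == age_to_band(a)]
      mult <- effective_multipliers(bundle$risk_set, d, a, cfg$min_risk_age)
      r <- status_specific_rate(p, eng$shares[t, ], mult)
      abs(sum(eng$shares[t, ] * r) - p)
    })
    tibble::tibble(cycle = t - 1L, age = a,
                   quantity = c("mortality", st_diseases()),
                   error = c(mort_err, dis))
  })
}
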