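# Transition schedule: annual initiation, quit and relapse probabilities, the
# per-age transition matrices over the 14-state space, and calibration of
# initiation/quit from cross-sectional banded prevalence.

#' Construct a transition schedule
#'
#' @param rates Tibble (`sex`, `age`, `initiation`, `quit`) covering every
#'   integer age from 15 to the horizon for each sex.
#' @param relapse List with `prob` (length-10 annual relapse probabilities for
#'   tunnel years 1-10, non-increasing) and `tail` (relapse in the 10+ state).
#' @return A list of class `st_schedule`.
#' @export
st_schedule <- function(rates, relapse = default_relapse()) {
  rates <- tibble::as_tibble(rates)
  stopifnot(all(c("sex", "age", "initiation", "quit") %in% names(rates)))
  p <- c(rates$initiation, rates$quit, relapse$prob, relapse$tail)
  if (any(p < 0 | p > 1)) {
    rlang::abort("schedule probabilities must lie in [0, 1]")
  }
  if (any(diff(relapse$prob) > 1e-12)) {
    rlang::abort("relapse probabilities must be non-increasing in time since quitting")
  }
  structure(list(rates = rates, relapse = relapse), class = "st_schedule")
}

# Fast lookup: named list by sex of vectors indexed by (age - 14).
schedule_lookup <- function(schedule, horizon_age) {
  by_sex <- split(schedule$rates, schedule$rates$sex)
  lapply(by_sex, function(d) {
    d <- d[order(d$age), ]
    ages <- 15:horizon_age
    idx <- match(ages, d$age)
    # hold the last observed age's value above the covered range
    idx[is.na(idx)] <- which.max(d$age)
    list(initiation = d$initiation[idx], quit = d$quit[idx])
  })
}

#' Build a one-cycle transition matrix
#'
#' Assembles the 14 x 14 annual transition matrix for one (sex, age). Death is
#' resolved first at the exposure-class-specific probability; behaviour change
#' applies to survivors: never users initiate with probability `initiation`,
#' current users quit into the first tunnel year with probability `quit`,
#' former users in tunnel year t relapse with probability `relapse$prob[t]`
#' or advance to year t+1 (year 10 advances to the long-term state), and
#' long-term former users relapse with probability `relapse$tail` or stay.
#'
#' @param initiation Annual probability never -> current.
#' @param quit Annual probability current -> first tunnel year.
#' @param relapse List with `prob` (length 10) and `tail`.
#' @param q_class Death probabilities per exposure class, ordered as
#'   [st_classes()].
#' @return A 14 x 14 row-stochastic matrix with dimnames [st_states()].
#' @export
build_transition_matrix <- function(initiation, quit, relapse, q_class) {
  states <- st_states()
  n <- length(states)
  probs <- c(initiation = initiation, quit = quit,
             stats::setNames(relapse$prob, paste0("relapse_", 1:10)),
             relapse_tail = relapse$tail,
             stats::setNames(q_class, paste0("q_", st_classes())))
  bad <- which(probs < 0 | probs > 1 | !is.finite(probs))
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "transition probability outside [0, 1]: ",
      paste0(names(probs)[bad], "=", format(probs[bad]), collapse = ", ")
    ))
  }
  P <- matrix(0, n, n, dimnames = list(states, states))
  q <- q_class[state_class_index()[1:13]]

  P[1, 14] <- q[1]
  P[1, 1] <- (1 - q[1]) * (1 - initiation)
  P[1, 2] <- (1 - q[1]) * initiation

  P[2, 14] <- q[2]
  P[2, 2] <- (1 - q[2]) * (1 - quit)
  P[2, 3] <- (1 - q[2]) * quit

  for (t in 1:10) {
    s <- 2 + t                        # former_t row
    nxt <- if (t < 10) s + 1 else 13  # advance; former_10 -> former_long
    P[s, 14] <- q[s]
    P[s, 2] <- (1 - q[s]) * relapse$prob[t]
    P[s, nxt] <- (1 - q[s]) * (1 - relapse$prob[t])
  }

  P[13, 14] <- q[13]
  P[13, 2] <- (1 - q[13]) * relapse$tail
  P[13, 13] <- (1 - q[13]) * (1 - relapse$tail)

  P[14, 14] <- 1
  P
}

# Exposure-class shares among the alive, from a 14-state occupancy vector.
class_shares <- function(occ) {
  idx <- state_class_index()[1:13]
  alive <- sum(occ[1:13])
  if (alive < 1e-300) return(stats::setNames(c(1, 0, 0, 0, 0), st_classes()))
  s <- vapply(1:5, function(k) sum(occ[1:13][idx == k]), numeric(1)) / alive
  stats::setNames(s, st_classes())
}

# Advance an occupancy vector one cycle at a given age; mortality is the
# life-table q apportioned over the vector's own alive exposure shares.
step_state <- function(occ, age, initiation, quit, relapse, q_all, mort_mult) {
  shares <- class_shares(occ)
  q_class <- status_specific_rate(q_all, shares, mort_mult)
  P <- build_transition_matrix(initiation, quit, relapse, q_class)
  as.numeric(occ %*% P)
}

# Project an occupancy vector over a run of single ages with constant
# initiation/quit, returning the final vector.
project_band <- function(occ, ages, initiation, quit, relapse,
                         q_by_age, mult_by_age) {
  for (a in ages) {
    occ <- step_state(occ, a, initiation, quit, relapse,
                      q_by_age[[as.character(a)]], mult_by_age[[as.character(a)]])
  }
  occ
}

# Shared setup for the calibrators: per-age mortality and multipliers for one sex.
calibration_context <- function(bundle, sex) {
  cfg <- bundle$config
  lt <- bundle$life_table[bundle$life_table$sex == sex, ]
  ages <- 15:cfg$horizon_age
  q <- stats::setNames(as.list(lt$q_all[match(ages, lt$age)]), ages)
  mult <- stats::setNames(lapply(ages, function(a) {
    effective_multipliers(bundle$risk_set, "mortality", a, cfg$min_risk_age)
  }), ages)
  prev <- bundle$use_prevalence[bundle$use_prevalence$sex == sex, ]
  bands <- cfg$entry_bands
  lo <- band_lower(bands)
  if (any(diff(lo) != 5)) rlang::abort("entry bands must be consecutive 5-year bands")
  prev <- prev[match(bands, prev$age_band), ]
  list(cfg = cfg, ages = ages, q = q, mult = mult, prev = prev,
       bands = bands, lo = lo)
}

solve_band_rate <- function(f, lower = 0, upper = 1, what, band) {
  flo <- f(lower); fhi <- f(upper)
  if (flo * fhi > 0) {
    # an endpoint that already matches to numerical precision is a root
    if (abs(flo) < 1e-12) return(lower)
    if (abs(fhi) < 1e-12) return(upper)
    # no root in [0, 1]: clamp to the nearer endpoint, never silently
    value <- if (abs(flo) <= abs(fhi)) lower else upper
    rlang::warn(paste0("calibration: no admissible ", what, " for band ", band,
                       "; clamped to ", value))
    return(value)
  }
  stats::uniroot(f, c(lower, upper), tol = 1e-14)$root
}

# One band's (initiation, quit) solved jointly by alternating 1-D root finds
# on the projected never and former shares at the next band.
solve_band <- function(occ, ages, targets, relapse, ctx, band,
                       fix_i = NULL, fix_c = NULL) {
  qb <- ctx$q[as.character(ages)]
  mb <- ctx$mult[as.character(ages)]
  proj <- function(i, c) {
    v <- project_band(occ, ages, i, c, relapse, qb, mb)
    alive <- sum(v[1:13])
    c(never = v[1] / alive,
      former = sum(v[3:13]) / alive)
  }
  i_cur <- if (is.null(fix_i)) 0 else fix_i
  c_cur <- if (is.null(fix_c)) 0 else fix_c
  for (iter in 1:100) {
    i_prev <- i_cur; c_prev <- c_cur
    if (is.null(fix_i)) {
      i_cur <- solve_band_rate(
        function(i) proj(i, c_cur)["never"] - targets["never"],
        what = "initiation", band = band)
    }
    if (is.null(fix_c)) {
      c_cur <- solve_band_rate(
        function(c) proj(i_cur, c)["former"] - targets["former"],
        what = "quit probability", band = band)
    }
    if (abs(i_cur - i_prev) < 1e-13 && abs(c_cur - c_prev) < 1e-13) break
  }
  list(initiation = i_cur, quit = c_cur)
}

calibrate_sex <- function(bundle, sex, relapse, fix_i = NULL, fix_c = NULL) {
  ctx <- calibration_context(bundle, sex)
  nb <- length(ctx$bands)
  occ <- initial_state_vector(bundle$use_prevalence, sex, ctx$bands[1],
                              former_split = ctx$cfg$former_split)
  out_i <- numeric(0); out_c <- numeric(0); out_age <- integer(0)
  for (b in seq_len(nb - 1)) {
    ages <- ctx$lo[b]:(ctx$lo[b] + 4)
    targets <- c(never = ctx$prev$never[b + 1],
                 former = ctx$prev$former[b + 1])
    sol <- solve_band(occ, ages, targets, relapse, ctx, ctx$bands[b + 1],
                      fix_i = if (is.null(fix_i)) NULL else fix_i[b],
                      fix_c = if (is.null(fix_c)) NULL else fix_c[b])
    occ <- project_band(occ, ages, sol$initiation, sol$quit, relapse,
                        ctx$q[as.character(ages)], ctx$mult[as.character(ages)])
    out_age <- c(out_age, ages)
    out_i <- c(out_i, rep(sol$initiation, 5))
    out_c <- c(out_c, rep(sol$quit, 5))
  }
  # hold the last calibrated band's values to the horizon
  rest <- (max(out_age) + 1):ctx$cfg$horizon_age
  tibble::tibble(
    sex = sex,
    age = c(out_age, rest),
    initiation = c(out_i, rep(out_i[length(out_i)], length(rest))),
    quit = c(out_c, rep(out_c[length(out_c)], length(rest)))
  )
}

#' Calibrate annual initiation probabilities
#'
#' For each pair of consecutive 5-year bands, finds the constant annual
#' probability of initiation (never to current) such that, after accounting
#' for differential survival across exposure classes, the projected never-user
#' share among the alive moves from the observed value at one band to the
#' observed value at the next over five annual cycles. Quit probabilities are
#' held at supplied values (default 0). Values are clamped to `[0, 1]` with a
#' warning when the observed shares are not reachable (e.g. never-user share
#' increasing with age).
#'
#' @param bundle An [st_bundle()].
#' @param sex `"male"` or `"female"`.
#' @param quit Optional per-band quit probabilities to hold fixed (length
#'   `length(entry_bands) - 1`); default all 0.
#' @param relapse Relapse schedule list; default [default_relapse()].
#' @return Tibble (`sex`, `age`, `initiation`, `quit`).
#' @export
calibrate_initiation <- function(bundle, sex, quit = NULL,
                                 relapse = default_relapse()) {
  nb <- length(bundle$config$entry_bands)
  if (is.null(quit)) quit <- rep(0, nb - 1)
  calibrate_sex(bundle, sex, relapse, fix_c = quit)
}

#' Calibrate annual quit probabilities
#'
#' For each pair of consecutive bands, root-finds the constant annual quit
#' probability such that the forward-projected former-user share at the next
#' band equals the observed former share, given initiation, relapse and
#' differential mortality. No admissible root leads to clamping with a
#' warning, never a silent failure.
#'
#' @inheritParams calibrate_initiation
#' @param initiation Per-band initiation probabilities to hold fixed (length
#'   `length(entry_bands) - 1`); default all 0.
#' @return Tibble (`sex`, `age`, `initiation`, `quit`).
#' @export
calibrate_quit <- function(bundle, sex, initiation = NULL,
                           relapse = default_relapse()) {
  nb <- length(bundle$config$entry_bands)
  if (is.null(initiation)) initiation <- rep(0, nb - 1)
  calibrate_sex(bundle, sex, relapse, fix_i = initiation)
}

#' Calibrate the full transition schedule
#'
#' Jointly calibrates initiation and quit probabilities for every sex by
#' alternating the two one-dimensional solves per band until convergence,
#' carrying the projected 14-state occupancy forward band by band so the
#' calibrated model reproduces the observed never/current/former shares at
#' every band boundary. Above the oldest observed band both probabilities are
#' held at their last calibrated values.
#'
#' @param bundle An [st_bundle()].
#' @param relapse Relapse schedule list; default [default_relapse()].
#' @return An [st_schedule()].
#' @export
calibrate_transitions <- function(bundle, relapse = default_relapse()) {
  rates <- purrr::map_dfr(bundle$config$sexes, function(sx) {
    calibrate_sex(bundle, sx, relapse)
  })
  st_schedule(rates, relapse)
}

#' Projected use-state prevalence under a schedule
#'
#' Runs the calibrated model forward from the youngest band and reports the
#' projected never/current/former shares among the alive at each band lower
#' bound, for comparison against the observed prevalence table
#' (self-consistency of the calibration).
#'
#' @param bundle An [st_bundle()].
#' @param schedule An [st_schedule()].
#' @return Tibble (`sex`, `age_band`, `state`, `observed`, `projected`).
#' @export
projected_prevalence <- function(bundle, schedule) {
  purrr::map_dfr(bundle$config$sexes, function(sx) {
    ctx <- calibration_context(bundle, sx)
    lk <- schedule_lookup(schedule, bundle$config$horizon_age)[[sx]]
    occ <- initial_state_vector(bundle$use_prevalence, sx, ctx$bands[1],
                                former_split = ctx$cfg$former_split)
    rows <- list()
    for (b in seq_along(ctx$bands)) {
      alive <- sum(occ[1:13])
      rows[[b]] <- tibble::tibble(
        sex = sx, age_band = ctx$bands[b],
        state = c("never", "current", "former"),
        observed = c(ctx$prev$never[b], ctx$prev$current[b], ctx$prev$former[b]),
        projected = c(occ[1], occ[2], sum(occ[3:13])) / alive
      )
      if (b < length(ctx$bands)) {
        ages <- ctx$lo[b]:(ctx$lo[b] + 4)
        for (a in ages) {
          k <- a - 14
          occ <- step_state(occ, a, lk$initiation[k], lk$quit[k],
                            schedule$relapse, ctx$q[[as.character(a)]],
                            ctx$mult[[as.character(a)]])
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Write / read a transition schedule as CSV
#'
#' Two files are written: `<stem>_rates.csv` (sex, age, initiation, quit) and
#' `<stem>_relapse.csv` (years_since_quit 1..10 plus a `tail` row), so a
#' schedule estimated elsewhere can be substituted verbatim.
#'
#' @param schedule An [st_schedule()].
#' @param stem Path stem (without extension).
#' @return `write_schedule` returns the written paths invisibly;
#'   `read_schedule` returns an [st_schedule()].
#' @export
write_schedule <- function(schedule, stem) {
  rates_path <- paste0(stem, "_rates.csv")
  relapse_path <- paste0(stem, "_relapse.csv")
  readr::write_csv(schedule$rates, rates_path)
  readr::write_csv(
    tibble::tibble(years_since_quit = c(as.character(1:10), "tail"),
                   prob = c(schedule$relapse$prob, schedule$relapse$tail)),
    relapse_path
  )
  invisible(c(rates_path, relapse_path))
}

#' @rdname write_schedule
#' @export
read_schedule <- function(stem) {
  rates <- readr::read_csv(paste0(stem, "_rates.csv"), show_col_types = FALSE)
  rl <- readr::read_csv(paste0(stem, "_relapse.csv"), show_col_types = FALSE)
  st_schedule(rates, list(prob = rl$prob[match(as.character(1:10), rl$years_since_quit)],
                          tail = rl$prob[rl$years_since_quit == "tail"]))
}
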