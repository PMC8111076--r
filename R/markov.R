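#' Markov model settings
#'
#' Defaults mirror the base case of the atezolizumab analysis: treatment is
#' given every 3 weeks, a 3-week cycle is treated as three quarters of a
#' month on the survival time axis, and a 10-year horizon is 174 such
#' cycles. Occupancy is credited at the start of each cycle (no half-cycle
#' correction); setting `half_cycle_correction = TRUE` switches to
#' trapezoidal accrual, which tracks the restricted mean survival time of
#' the overall-survival curve to well under 0.01 years. The discount clock
#' runs on model months divided by 12.
#'
#' @param cycle_length Cycle length in model months (default 0.75 = 3 weeks).
#' @param n_cycles Number of cycles (default 174, i.e. 10 years of 3-week
#'   cycles).
#' @param discount_rate Annual discount rate for costs and QALYs (0.05).
#' @param background_mortality Annual probability of death from causes other
#'   than the disease, applied as the PFS-to-death transition. Life-years and
#'   QALYs are invariant to it (deaths are reattributed between states, the
#'   overall survival curve still governs total occupancy).
#' @param half_cycle_correction Logical; `TRUE` uses trapezoidal occupancy.
#' @return An object of class `model_settings`.
#' @export
model_settings <- function(cycle_length = 0.75, n_cycles = 174,
                           discount_rate = 0.05, background_mortality = 0.01,
                           half_cycle_correction = FALSE) {
  stopifnot(
    cycle_length > 0, n_cycles >= 1,
    discount_rate >= 0, background_mortality >= 0, background_mortality < 1
  )
  structure(
    list(
      cycle_length = cycle_length, n_cycles = as.integer(n_cycles),
      discount_rate = discount_rate,
      background_mortality = background_mortality,
      half_cycle_correction = isTRUE(half_cycle_correction)
    ),
    class = "model_settings"
  )
}

# per-cycle probability from an annual probability
per_cycle_prob <- function(annual_prob, cycle_length) {
  1 - (1 - annual_prob)^(cycle_length / 12)
}

safe_ratio <- function(num, den) {
  out <- ifelse(den > 0, num / den, 0)
  pmin(pmax(out, 0), 1)
}

#' Time-dependent transition probabilities from fitted survival curves
#'
#' For cycle k ending at t = k * cycle_length: staying progression-free is
#' the conditional survival S_PFS(t) / S_PFS(t - mu); death from PFS is the
#' background mortality; progression takes the remainder (floored at zero).
#' Overall survival retention S_OS(t) / S_OS(t - mu) governs the total alive
#' mass, and the PD-to-PD probability is solved from the balance
#' \deqn{[(n_{PFS}+n_{PD}) P_{S\to S} - n_{PFS} P_{PFS\to PFS} -
#'   n_{PFS} P_{PFS\to PD}] / n_{PD}}
#' using the previous cycle's occupancies, then clamped to `[0, 1]`. When no
#' one is in PD the probability is defined as 1 (no mass to move). If the
#' PFS curve crosses above the OS curve the clamp empties PD and a warning
#' is emitted once.
#'
#' @param pfs,os [surv_dist()] curves for progression-free and overall
#'   survival (same time unit, months).
#' @param settings A [model_settings()].
#' @return A tibble with one row per cycle: `cycle`, `t_start`, `t_end`, the
#'   five transition probabilities, and the occupancies entering the cycle.
#' @export
transition_schedule <- function(pfs, os, settings = model_settings()) {
  stopifnot(inherits(pfs, "surv_dist"), inherits(os, "surv_dist"))
  engine <- markov_engine(pfs, os, settings)
  engine$schedule
}

# shared recursion: builds schedule and trace together so the occupancy-
# dependent PD row is consistent by construction
markov_engine <- function(pfs, os, settings) {
  mu <- settings$cycle_length
  K <- settings$n_cycles
  tk <- (0:K) * mu
  s_pfs <- surv_prob(pfs, tk)
  s_os <- surv_prob(os, tk)
  q_bg <- per_cycle_prob(settings$background_mortality, mu)

  n_pfs <- numeric(K + 1)
  n_pd <- numeric(K + 1)
  n_death <- numeric(K + 1)
  n_pfs[1] <- 1 # the whole cohort starts progression-free
  p <- matrix(NA_real_, nrow = K, ncol = 5)
  colnames(p) <- c("p_pfs_pfs", "p_pfs_pd", "p_pfs_death", "p_pd_pd", "p_pd_death")
  crossing_warned <- FALSE

  for (k in seq_len(K)) {
    stay <- safe_ratio(s_pfs[k + 1], s_pfs[k])
    p_ss <- safe_ratio(s_os[k + 1], s_os[k])
    tot_prev <- n_pfs[k] + n_pd[k]
    # PD occupancy the OS curve requires at the end of this cycle
    required_pd <- tot_prev * p_ss - n_pfs[k] * stay
    if (required_pd < -1e-9 && !crossing_warned) {
      warn("PFS curve exceeds OS curve over part of the horizon; PD occupancy clamped at 0")
      crossing_warned <- TRUE
    }
    required_pd <- max(required_pd, 0)
    # preferred PFS exit split: death at background mortality, rest progresses
    p_death_pref <- min(q_bg, 1 - stay)
    p_pd_pref <- 1 - stay - p_death_pref
    if (n_pd[k] > 1e-12) {
      raw <- (required_pd - n_pfs[k] * p_pd_pref) / n_pd[k]
      p_pd_pd <- min(max(raw, 0), 1)
    } else {
      p_pd_pd <- 1 # no mass to move
    }
    # the PFS->PD flow balances whatever PD retention cannot supply, so the
    # trace keeps tracking the OS curve; when the bracket clamps at 0 the
    # excess rapid progressors die within the cycle
    p_pd <- if (n_pfs[k] > 0) (required_pd - n_pd[k] * p_pd_pd) / n_pfs[k] else 0
    p_pd <- min(max(p_pd, 0), 1 - stay)
    p[k, ] <- c(stay, p_pd, 1 - stay - p_pd, p_pd_pd, 1 - p_pd_pd)
    n_pfs[k + 1] <- n_pfs[k] * stay
    n_pd[k + 1] <- n_pfs[k] * p_pd + n_pd[k] * p_pd_pd
    n_death[k + 1] <- 1 - n_pfs[k + 1] - n_pd[k + 1]
    if (n_pfs[k + 1] < -1e-12 || n_pd[k + 1] < -1e-12 ||
      n_death[k + 1] < n_death[k] - 1e-12) {
      abort("negative occupancy or decreasing deaths: survival curves are inconsistent")
    }
  }

  schedule <- tibble(
    cycle = seq_len(K),
    t_start = tk[-(K + 1)], t_end = tk[-1],
    p_pfs_pfs = p[, 1], p_pfs_pd = p[, 2], p_pfs_death = p[, 3],
    p_pd_pd = p[, 4], p_pd_death = p[, 5]
  )
  trace <- tibble(
    cycle = 0:K, t = tk,
    n_pfs = n_pfs, n_pd = n_pd, n_death = pmax(n_death, 0),
    incident_deaths = c(0, pmax(diff(n_death), 0))
  )
  attr(trace, "settings") <- settings
  class(trace) <- c("markov_trace", class(trace))
  attr(schedule, "settings") <- settings
  list(schedule = schedule, trace = trace)
}

#' Run the cohort trace from a transition schedule
#'
#' Applies the transition matrix recursion to a cohort starting 100% in the
#' progression-free state. `run_trace(transition_schedule(pfs, os, s), s)`
#' and [markov_trace()] give identical results.
#'
#' @param schedule Output of [transition_schedule()].
#' @param settings A [model_settings()]; defaults to the one the schedule
#'   was built with.
#' @return A `markov_trace` tibble: `cycle`, `t` (months), occupancies
#'   `n_pfs`, `n_pd`, `n_death`, and `incident_deaths` per cycle.
#' @export
run_trace <- function(schedule, settings = NULL) {
  settings <- settings %||% attr(schedule, "settings")
  stopifnot(inherits(settings, "model_settings"))
  K <- nrow(schedule)
  n_pfs <- numeric(K + 1)
  n_pd <- numeric(K + 1)
  n_death <- numeric(K + 1)
  n_pfs[1] <- 1
  for (k in seq_len(K)) {
    row <- schedule[k, ]
    n_pfs[k + 1] <- n_pfs[k] * row$p_pfs_pfs
    n_pd[k + 1] <- n_pfs[k] * row$p_pfs_pd + n_pd[k] * row$p_pd_pd
    n_death[k + 1] <- n_death[k] + n_pfs[k] * row$p_pfs_death + n_pd[k] * row$p_pd_death
    if (n_pfs[k + 1] < -1e-12 || n_pd[k + 1] < -1e-12) {
      abort("negative occupancy in trace")
    }
  }
  tk <- c(schedule$t_start[1], schedule$t_end)
  trace <- tibble(
    cycle = 0:K, t = tk,
    n_pfs = n_pfs, n_pd = n_pd, n_death = pmax(n_death, 0),
    incident_deaths = c(0, pmax(diff(n_death), 0))
  )
  attr(trace, "settings") <- settings
  class(trace) <- c("markov_trace", class(trace))
  trace
}

#' Build the cohort trace directly from survival curves
#'
#' @inheritParams transition_schedule
#' @return A `markov_trace` tibble (see [run_trace()]).
#' @export
markov_trace <- function(pfs, os, settings = model_settings()) {
  markov_engine(pfs, os, settings)$trace
}

# per-cycle occupancy basis: start-of-cycle values, or the trapezoidal mean
# when half-cycle correction is on; one row per cycle 1..K
occupancy_basis <- function(trace, settings = NULL) {
  settings <- settings %||% attr(trace, "settings")
  K <- nrow(trace) - 1L
  first <- seq_len(K)
  second <- first + 1L
  if (isTRUE(settings$half_cycle_correction)) {
    tibble(
      cycle = seq_len(K),
      pfs = (trace$n_pfs[first] + trace$n_pfs[second]) / 2,
      pd = (trace$n_pd[first] + trace$n_pd[second]) / 2
    )
  } else {
    tibble(cycle = seq_len(K), pfs = trace$n_pfs[first], pd = trace$n_pd[first])
  }
}

#' Life-years of a cohort trace
#'
#' Undiscounted person-time alive, in years, accumulated per cycle with the
#' occupancy basis implied by the trace's settings.
#'
#' @param trace A `markov_trace`.
#' @return Life-years (scalar).
#' @export
trace_life_years <- function(trace) {
  settings <- attr(trace, "settings")
  occ <- occupancy_basis(trace, settings)
  sum(occ$pfs + occ$pd) * settings$cycle_length / 12
}
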