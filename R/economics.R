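#' Health-state utilities
#'
#' Defaults are the published values for metastatic NSCLC: 0.804
#' progression-free, 0.321 progressed, 0 dead.
#'
#' @param u_pfs,u_pd,u_death Utilities in `[0, 1]`.
#' @return An object of class `utility_set`.
#' @export
utility_set <- function(u_pfs = 0.804, u_pd = 0.321, u_death = 0) {
  vals <- c(u_pfs = u_pfs, u_pd = u_pd, u_death = u_death)
  if (any(vals < 0 | vals > 1)) abort("utilities must lie in [0, 1]")
  structure(as.list(vals), class = "utility_set")
}

#' Patient-assistance program drug schedule
#'
#' The atezolizumab program: the patient pays for the first `paid_cycles`
#' cycles, receives the next `free_cycles` free, and the pattern repeats
#' while treatment continues.
#'
#' @param paid_cycles,free_cycles Cycle counts (default 2 paid, 3 free).
#' @param repeating If `FALSE`, all cycles after the first `paid_cycles`
#'   are free.
#' @return An object of class `pap_schedule`.
#' @export
pap_schedule <- function(paid_cycles = 2, free_cycles = 3, repeating = TRUE) {
  stopifnot(paid_cycles >= 0, free_cycles >= 0, paid_cycles + free_cycles > 0)
  structure(
    list(
      paid_cycles = as.integer(paid_cycles),
      free_cycles = as.integer(free_cycles),
      repeating = isTRUE(repeating)
    ),
    class = "pap_schedule"
  )
}

#' Economic inputs for one treatment strategy
#'
#' All costs are per the configured currency (USD in the shipped synthetic
#' configs) and all "per cycle" quantities refer to the model cycle
#' (3 weeks). Drug and supportive/follow-up costs accrue while the cohort
#' occupies the treated states; second-line treatment accrues in PD for the
#' treated fraction; end-of-life cost is charged once per incident death;
#' serious-adverse-event (SAE) costs and disutilities are charged once in
#' the first cycle.
#'
#' @param arm_label Strategy name.
#' @param drug_cost_per_cycle Acquisition cost per treatment cycle.
#' @param treatment_in States in which the drug is given (default `"pfs"`).
#' @param max_treatment_cycles Optional cap on treated cycles.
#' @param pap Optional [pap_schedule()].
#' @param saes Optional tibble of included SAEs for this arm with columns
#'   `name`, `incidence`, `cost`, `disutility` (see [sae_filter()]).
#' @param supportive_care_cost_per_cycle,followup_cost_per_cycle Per-cycle
#'   costs while alive.
#' @param end_of_life_cost Terminal-care cost per incident death.
#' @param second_line_fraction,second_line_cost_per_cycle Fraction of PD
#'   patients on second-line treatment and its per-cycle cost.
#' @param currency Currency code annotation.
#' @return An object of class `strategy_config`.
#' @export
strategy_config <- function(arm_label,
                            drug_cost_per_cycle,
                            treatment_in = "pfs",
                            max_treatment_cycles = Inf,
                            pap = NULL,
                            saes = NULL,
                            supportive_care_cost_per_cycle = 0,
                            followup_cost_per_cycle = 0,
                            end_of_life_cost = 0,
                            second_line_fraction = 0,
                            second_line_cost_per_cycle = 0,
                            currency = "USD") {
  costs <- c(
    drug_cost_per_cycle, supportive_care_cost_per_cycle,
    followup_cost_per_cycle, end_of_life_cost, second_line_cost_per_cycle
  )
  if (any(costs < 0)) abort("costs must be >= 0")
  if (second_line_fraction < 0 || second_line_fraction > 1) {
    abort("second_line_fraction must lie in [0, 1]")
  }
  if (!is.null(pap)) stopifnot(inherits(pap, "pap_schedule"))
  if (!is.null(saes)) {
    stopifnot(all(c("name", "incidence", "cost", "disutility") %in% names(saes)))
    if (any(saes$incidence < 0 | saes$incidence > 1)) abort("SAE incidences must lie in [0, 1]")
    if (any(saes$disutility < 0)) abort("SAE disutilities must be >= 0")
  }
  treatment_in <- match.arg(treatment_in, c("pfs", "pd"), several.ok = TRUE)
  structure(
    list(
      arm_label = arm_label,
      drug_cost_per_cycle = drug_cost_per_cycle,
      treatment_in = treatment_in,
      max_treatment_cycles = max_treatment_cycles,
      pap = pap,
      saes = if (is.null(saes)) NULL else as_tibble(saes),
      supportive_care_cost_per_cycle = supportive_care_cost_per_cycle,
      followup_cost_per_cycle = followup_cost_per_cycle,
      end_of_life_cost = end_of_life_cost,
      second_line_fraction = second_line_fraction,
      second_line_cost_per_cycle = second_line_cost_per_cycle,
      currency = currency
    ),
    class = "strategy_config"
  )
}

#' Keep only serious adverse events that differ materially between arms
#'
#' The costing rule: an SAE (grade >= 3) enters the model only when its
#' incidence differs by at least `threshold` (default 3 percentage points)
#' between the two strategies. Included SAEs are charged once, in the first
#' cycle.
#'
#' @param sae_candidates Tibble with columns `name`, `incidence_a`,
#'   `incidence_b`, `cost`, `disutility`.
#' @param threshold Minimum absolute incidence difference (default 0.03).
#' @return The filtered tibble, with an `included` logical column dropped
#'   rows removed.
#' @examples
#' sae_filter(tibble::tibble(
#'   name = c("anemia", "fatigue"), incidence_a = c(0.10, 0.04),
#'   incidence_b = c(0.05, 0.02), cost = c(500, 250), disutility = c(0.07, 0.05)
#' ))
#' @export
sae_filter <- function(sae_candidates, threshold = 0.03) {
  stopifnot(all(c("name", "incidence_a", "incidence_b", "cost", "disutility") %in%
    names(sae_candidates)))
  dplyr::filter(
    as_tibble(sae_candidates),
    abs(.data$incidence_a - .data$incidence_b) >= threshold
  )
}

#' Drug acquisition cost at a given cycle
#'
#' Returns the cost charged for the drug at cycle `k` (1-based), before
#' weighting by treated-state occupancy: zero beyond `max_treatment_cycles`,
#' and zero in the free positions of a patient-assistance schedule (with the
#' default 2-paid/3-free repeating program, cycles 1, 2, 6, 7, 11, 12, ...
#' are paid).
#'
#' @param cfg A [strategy_config()].
#' @param k Cycle index (vectorized, >= 1).
#' @return Cost per cycle (same length as `k`).
#' @export
drug_cost_at_cycle <- function(cfg, k) {
  stopifnot(inherits(cfg, "strategy_config"), all(k >= 1))
  cost <- rep(cfg$drug_cost_per_cycle, length(k))
  cost[k > cfg$max_treatment_cycles] <- 0
  if (!is.null(cfg$pap)) {
    pap <- cfg$pap
    if (pap$repeating) {
      pos <- (k - 1) %% (pap$paid_cycles + pap$free_cycles)
      cost[pos >= pap$paid_cycles] <- 0
    } else {
      cost[k > pap$paid_cycles] <- 0
    }
  }
  cost
}

#' Attach costs and utilities to a trace and discount
#'
#' Per cycle k (occupancy basis per the trace settings, discount factor
#' `(1 + r)^(-t/12)` at the cycle-start clock time): QALYs are utility-
#' weighted person-time, discounted; life-years are undiscounted; drug costs
#' are weighted by treated-state occupancy; supportive-care and follow-up
#' costs by alive occupancy; second-line costs by PD occupancy times the
#' treated fraction; end-of-life cost by incident deaths; SAE costs and
#' disutilities fall entirely in cycle 1.
#'
#' @param trace A `markov_trace`.
#' @param cfg A [strategy_config()].
#' @param utilities A [utility_set()].
#' @param discount_rate Annual discount rate; defaults to the trace
#'   settings.
#' @return An object of class `economic_result` with totals and a per-cycle
#'   breakdown.
#' @export
accumulate <- function(trace, cfg, utilities = utility_set(),
                       discount_rate = NULL) {
  stopifnot(inherits(trace, "markov_trace"), inherits(cfg, "strategy_config"))
  settings <- attr(trace, "settings")
  r <- discount_rate %||% settings$discount_rate
  mu <- settings$cycle_length
  K <- nrow(trace) - 1L
  occ <- occupancy_basis(trace, settings)
  k <- occ$cycle
  t_start <- trace$t[k] # clock time at cycle start
  v <- (1 + r)^(-t_start / 12)
  cycle_years <- mu / 12

  ly_cycle <- (occ$pfs + occ$pd) * cycle_years
  qaly_cycle <- (occ$pfs * utilities$u_pfs + occ$pd * utilities$u_pd) *
    cycle_years * v

  treated_occ <- rowSums(cbind(
    if ("pfs" %in% cfg$treatment_in) occ$pfs else 0,
    if ("pd" %in% cfg$treatment_in) occ$pd else 0
  ))
  drug <- drug_cost_at_cycle(cfg, k) * treated_occ * v
  routine <- (cfg$supportive_care_cost_per_cycle + cfg$followup_cost_per_cycle) *
    (occ$pfs + occ$pd) * v
  second_line <- cfg$second_line_fraction * cfg$second_line_cost_per_cycle *
    occ$pd * v
  eol <- cfg$end_of_life_cost * trace$incident_deaths[k + 1] * v

  sae_cost <- 0
  sae_disutility <- 0
  if (!is.null(cfg$saes) && nrow(cfg$saes) > 0) {
    sae_cost <- sum(cfg$saes$incidence * cfg$saes$cost)
    sae_disutility <- sum(cfg$saes$incidence * cfg$saes$disutility)
  }
  cost_cycle <- drug + routine + second_line + eol
  cost_cycle[1] <- cost_cycle[1] + sae_cost # first cycle, undiscounted clock t = 0
  qaly_cycle[1] <- qaly_cycle[1] - sae_disutility

  breakdown <- tibble(
    cycle = k, t_start = t_start, discount = v,
    ly = ly_cycle, qaly = qaly_cycle,
    cost_drug = drug, cost_routine = routine,
    cost_second_line = second_line, cost_end_of_life = eol
  )
  structure(
    list(
      arm_label = cfg$arm_label,
      total_cost = sum(cost_cycle),
      total_ly = sum(ly_cycle),
      total_qaly = sum(qaly_cycle),
      discount_rate = r,
      currency = cfg$currency,
      breakdown = breakdown
    ),
    class = "economic_result"
  )
}

#' @export
print.economic_result <- function(x, ...) {
  cat(sprintf(
    "<economic_result> %s: cost %s%.2f, %.3f LYs, %.3f QALYs (discounted at %.1f%%)\n",
    x$arm_label, x$currency, x$total_cost, x$total_ly, x$total_qaly,
    100 * x$discount_rate
  ))
  invisible(x)
}

#' Incremental cost-effectiveness ratio
#'
#' @param res_treatment,res_comparator [accumulate()] results from the same
#'   model settings.
#' @return An object of class `icer_result`: incremental cost, QALYs,
#'   life-years, the ICER (NA when the QALY difference is zero), and a
#'   dominance flag (`"dominant"` = cheaper and more effective,
#'   `"dominated"` = dearer and less effective).
#' @export
icer <- function(res_treatment, res_comparator) {
  stopifnot(
    inherits(res_treatment, "economic_result"),
    inherits(res_comparator, "economic_result")
  )
  dc <- res_treatment$total_cost - res_comparator$total_cost
  dq <- res_treatment$total_qaly - res_comparator$total_qaly
  dl <- res_treatment$total_ly - res_comparator$total_ly
  undefined <- abs(dq) < 1e-12
  dominance <- "none"
  if (!undefined && dq > 0 && dc < 0) dominance <- "dominant"
  if (!undefined && dq < 0 && dc > 0) dominance <- "dominated"
  structure(
    list(
      treatment = res_treatment$arm_label,
      comparator = res_comparator$arm_label,
      delta_cost = dc, delta_qaly = dq, delta_ly = dl,
      icer = if (undefined) NA_real_ else dc / dq,
      undefined = undefined, dominance = dominance,
      currency = res_treatment$currency
    ),
    class = "icer_result"
  )
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf(
    "<icer_result> %s vs %s: delta cost %s%.2f, delta QALY %.3f -> ICER %s\n",
    x$treatment, x$comparator, x$currency, x$delta_cost, x$delta_qaly,
    if (x$undefined) "undefined" else sprintf("%.2f/QALY", x$icer)
  ))
  if (x$dominance != "none") cat(sprintf("  (%s)\n", x$dominance))
  invisible(x)
}

#' Per-administration drug cost from unit price and dose
#'
#' Linear per-mg pricing (no vial rounding). Dose can be flat in mg or per
#' square metre of body surface area; the reference patient has a BSA of
#' 1.72 m^2.
#'
#' @param price_per_mg Unit price.
#' @param dose_mg Flat dose in mg (e.g. 1200 for atezolizumab).
#' @param dose_mg_per_m2 Dose in mg/m^2 (e.g. 500 for pemetrexed).
#' @param bsa Body surface area in m^2.
#' @return Cost per administration.
#' @export
drug_cost_from_dose <- function(price_per_mg, dose_mg = NULL,
                                dose_mg_per_m2 = NULL, bsa = 1.72) {
  if (is.null(dose_mg) == is.null(dose_mg_per_m2)) {
    abort("give exactly one of dose_mg or dose_mg_per_m2")
  }
  dose <- dose_mg %||% (dose_mg_per_m2 * bsa)
  stopifnot(price_per_mg >= 0, dose >= 0)
  price_per_mg * dose
}

#' Convert CNY amounts to USD
#'
#' @param x Amounts in CNY.
#' @param rate CNY per USD (2019 analysis rate 6.899).
#' @return Amounts in USD.
#' @export
cny_to_usd <- function(x, rate = 6.899) x / rate
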